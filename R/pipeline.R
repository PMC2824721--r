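defaultConfig <- function() {
  list(
    seed = 1L,
    simulate = list(n_genes = 500L),
    integrate = list(regions = c("genome", "promoter", "TSS")),
    profiles = list(flank = 800L, smooth_window = 31L,
                    min_separation = 100L, gap_threshold = 200L),
    metrics = list(flank = 800L, snr_window = 200L),
    regulation = list(k = 4L, restarts = 10L, lrc_widths = c(100L, 600L),
                      lrc_width_step = 50L, lrc_position_step = 8L,
                      n_boot = 200L),
    sliding = list(n_boot = 500L)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the integration pipeline end to end
#'
#' Executes the requested stages in dependency order
#' (simulate, integrate, profiles, metrics, regulation, sliding) on a
#' synthetic study, writing every result as TSV/BED/bedGraph under
#' \code{outDir} plus a manifest with MD5 checksums. Stages consume the
#' in-memory results of earlier stages in the same call; a stage whose
#' prerequisite was neither run nor already on disk fails fast naming the
#' missing input.
#'
#' @param config a YAML file path or nested list overriding
#'   \code{nucensemble:::defaultConfig()}.
#' @param outDir output directory (created if absent).
#' @param stages subset of \code{c("simulate", "integrate", "profiles",
#'   "metrics", "regulation", "sliding")}, or \code{"all"}.
#' @param seed overrides the config seed when given.
#' @return invisibly, a data.frame manifest (file, md5).
#' @export
runPipeline <- function(config = list(), outDir = "nucensemble_out",
                        stages = "all", seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  allStages <- c("simulate", "integrate", "profiles", "metrics",
                 "regulation", "sliding")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- allStages[allStages %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  state <- new.env(parent = emptyenv())

  needSim <- function() {
    if (!is.null(state$sim)) return(invisible())
    annoPath <- file.path(outDir, "annotation.tsv")
    if (!file.exists(annoPath))
      stop("missing upstream artifact for this stage: ", annoPath,
           " (run the 'simulate' stage first)")
    # rebuild the simulation deterministically from the stored config
    cfgPath <- file.path(outDir, "config.yaml")
    if (!file.exists(cfgPath))
      stop("missing upstream artifact: ", cfgPath)
    stored <- yaml::read_yaml(cfgPath)
    state$sim <- simulateFromConfig(mergeConfig(defaultConfig(), stored))
    invisible()
  }
  simulateFromConfig <- function(cfg) {
    pars <- do.call(architectureParams,
                    c(cfg$simulate, list(seed = cfg$seed)))
    simulateStudy(pars)
  }

  for (stage in stages) {
    message("[nucensemble] stage: ", stage)
    switch(stage,
      simulate = {
        yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
        emit(file.path(outDir, "config.yaml"))
        state$sim <- simulateFromConfig(cfg)
        sim <- state$sim
        emit(writeAnnotation(sim$annotation,
                             file.path(outDir, "annotation.tsv")))
        for (cs in sim$callsets)
          emit(writeCalls(cs, file.path(outDir,
                                        sprintf("calls_%s.bed", cs@name))))
        emit(writeCalls(sim$positionedBefore,
                        file.path(outDir, "calls_positioned_normal.bed")))
        emit(writeCalls(sim$positionedAfter,
                        file.path(outDir, "calls_positioned_heat.bed")))
        emit(writeTsv(sim$properties, file.path(outDir, "properties.tsv")))
        emit(writeTsv(layoutNucleosomes(sim$layout),
                      file.path(outDir, "truth_nucleosomes.tsv")))
        emit(writeTsv(genes(sim$layout),
                      file.path(outDir, "truth_genes.tsv")))
      },
      integrate = {
        needSim()
        sim <- state$sim
        state$stable <- logicalAndStack(sim$tracks)
        state$xor <- xorMeanStack(sim$tracks)
        state$bdid <- bdidDecompose(sim$tracks)
        emit(writeTrack(state$stable, file.path(outDir, "stable.bedGraph")))
        emit(writeTrack(state$xor, file.path(outDir, "dynamic.bedGraph")))
        for (kk in names(state$bdid@profiles))
          emit(writeTrack(state$bdid@profiles[[kk]],
                          file.path(outDir, sprintf("bdid_%s.bedGraph", kk))))
        reps <- datasetCorrelations(sim$tracks, sim$annotation,
                                    cfg$integrate$regions)
        for (rep in reps)
          emit(writeTsv(as.data.frame(rep$r),
                        file.path(outDir,
                                  sprintf("correlation_%s.tsv", rep$region))))
      },
      profiles = {
        needSim(); needIntegrated(state, outDir, cfg)
        sim <- state$sim
        pc <- cfg$profiles
        state$stableComposite <- compositeProfile(
          alignToAnchor(state$stable, sim$annotation, "TSS", pc$flank))
        state$xorComposite <- compositeProfile(
          alignToAnchor(state$xor, sim$annotation, "TSS", pc$flank))
        state$stablePeaks <- detectPeaks(state$stableComposite,
                                         pc$smooth_window,
                                         pc$min_separation)
        sp <- peakSpacing(state$stablePeaks, pc$gap_threshold)
        emit(writeTsv(data.frame(offset = state$stableComposite@offsets,
                                 stable = state$stableComposite@signal,
                                 dynamic = state$xorComposite@signal),
                      file.path(outDir, "composite_tss.tsv")))
        emit(writeTsv(data.frame(peak_offset = peakOffsets(state$stablePeaks),
                                 height = state$stablePeaks@heights),
                      file.path(outDir, "stable_peaks.tsv")))
        emit(writeTsv(data.frame(mean_spacing = sp$meanSpacing,
                                 n_spacings = length(sp$spacings),
                                 n_gaps = length(sp$gaps)),
                      file.path(outDir, "stable_peak_spacing.tsv")))
      },
      metrics = {
        needSim(); needIntegrated(state, outDir, cfg)
        sim <- state$sim
        meas <- geneMeasurability(sim$tracks, sim$annotation,
                                  cfg$metrics$flank)
        sMat <- alignToAnchor(state$stable, sim$annotation, "TSS",
                              cfg$metrics$flank)
        dMat <- alignToAnchor(state$xor, sim$annotation, "TSS",
                              cfg$metrics$flank)
        snrTab <- geneSnrTable(sMat, dMat)
        perGene <- merge(meas, snrTab, by = "gene_id")
        perGene$snr_db[!is.finite(perGene$snr_db)] <- NA
        emit(writeTsv(perGene, file.path(outDir, "gene_metrics.tsv")))
        emit(writeTsv(snrCurve(compositeProfile(sMat),
                               compositeProfile(dMat),
                               cfg$metrics$snr_window),
                      file.path(outDir, "snr_curve.tsv")))
      },
      regulation = {
        needSim(); needIntegrated(state, outDir, cfg)
        sim <- state$sim
        propPath <- file.path(outDir, "properties.tsv")
        props <- sim$properties
        rc <- cfg$regulation
        stableMap <- bdidGroupTrack(state$bdid, "stable")
        feat <- occupancyFeatureMatrix(stableMap, sim$annotation, 1600L)
        clus <- clusterGenes(feat, rc$k, rc$restarts, cfg$seed)
        emit(writeTsv(data.frame(gene_id = names(clus$assignment),
                                 cluster = clus$assignment),
                      file.path(outDir, "clusters.tsv")))
        prop1 <- stats::setNames(props[[2L]], props$gene_id)
        emit(writeTsv(groupFrequencyCurves(clus$assignment, prop1),
                      file.path(outDir, "group_frequency.tsv")))
        dFeat <- occupancyFeatureMatrix(state$xor, sim$annotation, 1600L)
        sFeat <- occupancyFeatureMatrix(state$stable, sim$annotation, 1600L)
        widths <- seq(rc$lrc_widths[1L], rc$lrc_widths[2L],
                      by = rc$lrc_width_step)
        emit(writeTsv(lrcMap(dFeat, prop1, widths, rc$lrc_position_step),
                      file.path(outDir, "lrc_dynamic.tsv")))
        emit(writeTsv(lrcMap(sFeat, prop1, widths, rc$lrc_position_step),
                      file.path(outDir, "lrc_stable.tsv")))
        stableCalls <- callsFromBinaryTrack(thresholdTrack(stableMap, 0.5))
        tc <- tataContrast(stableCalls, sim$annotation, props,
                           nBoot = rc$n_boot, seed = cfg$seed)
        emit(writeTsv(tc$plusOne, file.path(outDir, "tata_plus_one.tsv")))
        emit(writeTsv(data.frame(difference = tc$difference$estimate,
                                 low = tc$difference$low,
                                 high = tc$difference$high),
                      file.path(outDir, "tata_difference.tsv")))
      },
      sliding = {
        needSim()
        sim <- state$sim
        idxB <- indexNucleosomes(sim$positionedBefore, sim$annotation)
        idxA <- indexNucleosomes(sim$positionedAfter, sim$annotation)
        cls <- stats::setNames(genes(sim$layout)$class,
                               genes(sim$layout)$gene_id)
        disp <- displacementByIndex(idxB, idxA, cls,
                                    nBoot = cfg$sliding$n_boot,
                                    seed = cfg$seed)
        emit(writeTsv(disp, file.path(outDir, "sliding_displacement.tsv")))
        eqMap <- equilibriumIndexMap(sim$params$equilibrium_offsets)
        conv <- equilibriumConvergence(idxB, idxA, eqMap, cls)
        emit(writeTsv(conv$perGene, file.path(outDir,
                                              "sliding_patterns.tsv")))
        emit(writeTsv(conv$byIndex,
                      file.path(outDir, "sliding_by_index.tsv")))
        dens <- do.call(rbind, lapply(1:4, function(ix) {
          offs <- idxB$offset[idxB$index == ix]
          offsA <- idxA$offset[idxA$index == ix]
          rbind(cbind(index = ix, condition = "normal",
                      dyadKernelDensity(offs)),
                cbind(index = ix, condition = "heat_shock",
                      dyadKernelDensity(offsA)))
        }))
        emit(writeTsv(dens, file.path(outDir, "dyad_density.tsv")))
        pat <- stats::setNames(conv$perGene$pattern, conv$perGene$gene_id)
        enr <- patternEnrichmentTest(pat, cls)
        emit(writeTsv(data.frame(p = enr$p, method = enr$method,
                                 odds_ratio = enr$odds_ratio),
                      file.path(outDir, "sliding_enrichment.tsv")))
      })
  }
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  invisible(manifest)
}

# ensure the integrated consensus tracks exist in the pipeline state,
# recomputing them from the simulation when the stage was skipped but its
# inputs exist
needIntegrated <- function(state, outDir, cfg) {
  if (!is.null(state$stable)) return(invisible())
  if (is.null(state$sim))
    stop("missing upstream artifact: integrated tracks need the ",
         "'simulate' stage")
  state$stable <- logicalAndStack(state$sim$tracks)
  state$xor <- xorMeanStack(state$sim$tracks)
  state$bdid <- bdidDecompose(state$sim$tracks)
  invisible()
}
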