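#' Parameters of the synthetic nucleosome architecture
#'
#' Bundles and validates every knob of the synthetic genome: gene placement,
#' the phased stable-nucleosome array (equilibrium offsets relative to the
#' TSS), counterphase dynamic nucleosomes, TATA-dependent +1 offsets,
#' promoter archetypes and promoter response classes.
#'
#' The default equilibrium offsets are the eight canonical stable
#' equilibrium points (-559, -393, -228, +60, +225, +392, +559, +725 bp
#' relative to the TSS), giving adjacent spacings of 165-167 bp outside the
#' promoter nucleosome-free region. The +1 position is drawn around 58 bp
#' (TATA-containing) or 64 bp (TATA-free) rather than the generic +60.
#'
#' @param n_genes number of genes to place.
#' @param chrom_length chromosome length in bp; \code{NULL} sizes the
#'   chromosome to fit \code{n_genes} at \code{gene_spacing} plus margins.
#' @param gene_spacing distance between consecutive TSS slots (bp).
#' @param gene_length TSS-to-TTS length (bp).
#' @param margin clearance kept free at both chromosome ends (bp).
#' @param nfr_span promoter nucleosome-free region, bp relative to TSS
#'   (ordered pair); no stable dyad is planted inside it.
#' @param equilibrium_offsets ascending stable-nucleosome offsets (bp
#'   relative to TSS, strand-oriented).
#' @param stable_jitter_sd per-gene positional SD of stable dyads (bp).
#' @param dynamic_jitter_sd per-observation positional SD of dynamic dyads
#'   (bp); resampled for every platform.
#' @param dynamic_presence_prob baseline probability that a dynamic
#'   nucleosome is present in any one platform's sample.
#' @param footprint nucleosome footprint width (bp).
#' @param tata_fraction fraction of TATA-containing genes.
#' @param plus_one_offset_tata,+1 dyad mean offset for TATA-containing genes.
#' @param plus_one_offset_tatafree +1 dyad mean offset for TATA-free genes.
#' @param archetype_fractions named fractions of the four promoter
#'   occupancy archetypes \code{full}, \code{downstream}, \code{upstream},
#'   \code{none} (which stable equilibrium positions are occupied).
#' @param archetype_dynamic_mult named multipliers applied to
#'   \code{dynamic_presence_prob} per archetype (all 1 by default: with
#'   dynamic nucleosomes planted only where the stable array is absent,
#'   occupancy contrast between archetypes is structural).
#' @param promoter_class_fractions named fractions of promoter response
#'   classes \code{activated}, \code{repressed}, \code{basal}.
#' @param seed integer seed making every generator call reproducible.
#' @return a validated list of class \code{"ArchitectureParams"}.
#' @export
architectureParams <- function(n_genes = 2000,
                               chrom_length = NULL,
                               gene_spacing = 2400,
                               gene_length = 1200,
                               margin = 2000,
                               nfr_span = c(-180L, 0L),
                               equilibrium_offsets = c(-559L, -393L, -228L,
                                                       60L, 225L, 392L,
                                                       559L, 725L),
                               stable_jitter_sd = 8,
                               dynamic_jitter_sd = 25,
                               dynamic_presence_prob = 0.55,
                               footprint = 147L,
                               tata_fraction = 0.2,
                               plus_one_offset_tata = 58L,
                               plus_one_offset_tatafree = 64L,
                               archetype_fractions = c(full = 0.25,
                                                       downstream = 0.25,
                                                       upstream = 0.25,
                                                       none = 0.25),
                               archetype_dynamic_mult = c(full = 1,
                                                          downstream = 1,
                                                          upstream = 1,
                                                          none = 1),
                               promoter_class_fractions = c(activated = 0.15,
                                                            repressed = 0.15,
                                                            basal = 0.70),
                               seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
            gene_spacing = as.integer(gene_spacing),
            gene_length = as.integer(gene_length),
            margin = as.integer(margin),
            nfr_span = as.integer(nfr_span),
            equilibrium_offsets = as.integer(equilibrium_offsets),
            stable_jitter_sd = stable_jitter_sd,
            dynamic_jitter_sd = dynamic_jitter_sd,
            dynamic_presence_prob = dynamic_presence_prob,
            footprint = as.integer(footprint),
            tata_fraction = tata_fraction,
            plus_one_offset_tata = as.integer(plus_one_offset_tata),
            plus_one_offset_tatafree = as.integer(plus_one_offset_tatafree),
            archetype_fractions = archetype_fractions,
            archetype_dynamic_mult = archetype_dynamic_mult,
            promoter_class_fractions = promoter_class_fractions,
            seed = as.integer(seed))
  if (p$n_genes < 1L) stop("n_genes must be >= 1")
  if (length(p$nfr_span) != 2L || p$nfr_span[1L] > p$nfr_span[2L])
    stop("nfr_span must be an ordered (low, high) pair")
  if (is.unsorted(p$equilibrium_offsets, strictly = TRUE))
    stop("equilibrium_offsets must be strictly ascending")
  if (p$stable_jitter_sd < 0 || p$dynamic_jitter_sd < 0)
    stop("jitter SDs must be >= 0")
  for (pr in c(p$dynamic_presence_prob, p$tata_fraction))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  if (p$footprint < 1L) stop("footprint must be >= 1")
  if (abs(sum(p$archetype_fractions) - 1) > 1e-8 ||
      abs(sum(p$promoter_class_fractions) - 1) > 1e-8)
    stop("archetype and promoter class fractions must each sum to 1")
  if (!all(c("full", "downstream", "upstream", "none") %in%
           names(p$archetype_fractions)))
    stop("archetype_fractions must name full/downstream/upstream/none")
  if (is.null(p$chrom_length))
    p$chrom_length <- 2L * p$margin + p$n_genes * p$gene_spacing
  p$chrom_length <- as.integer(p$chrom_length)
  class(p) <- "ArchitectureParams"
  p
}

#' Generate a synthetic genome annotation
#'
#' Places \code{n_genes} TSSs on one chromosome at \code{gene_spacing}
#' intervals (with +/-200 bp uniform jitter), alternating placement keeps
#' every TSS +/- 800 bp window disjoint. Strands are drawn 50/50, TATA
#' labels at \code{tata_fraction}, promoter response classes at
#' \code{promoter_class_fractions}.
#'
#' @param params an \code{\link{architectureParams}} object.
#' @return a \code{\linkS4class{GenomeAnnotation}}.
#' @export
makeAnnotation <- function(params = architectureParams()) {
  stopifnot(inherits(params, "ArchitectureParams"))
  need <- 2L * params$margin + params$n_genes * params$gene_spacing
  if (params$chrom_length < need)
    stop(sprintf(paste("chromosome too short: %d genes at spacing %d with",
                       "margin %d need %d bp, have %d"),
                 params$n_genes, params$gene_spacing, params$margin,
                 need, params$chrom_length))
  withSeed(deriveSeed(params$seed, "annotation"), {
    n <- params$n_genes
    slot0 <- params$margin + params$gene_spacing %/% 2L
    tss <- slot0 + (seq_len(n) - 1L) * params$gene_spacing +
      as.integer(round(stats::runif(n, -200, 200)))
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    tts <- as.integer(ifelse(strand == "+", tss + params$gene_length,
                             tss - params$gene_length))
    tata <- stats::runif(n) < params$tata_fraction
    cls <- sample(names(params$promoter_class_fractions), n, replace = TRUE,
                  prob = params$promoter_class_fractions)
    g <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                    chrom = "chrI", strand = strand,
                    tss = as.integer(tss), tts = tts,
                    tata = tata, class = cls,
                    stringsAsFactors = FALSE)
    new("GenomeAnnotation", genes = g,
        chromSizes = c(chrI = params$chrom_length))
  })
}

archetypeMask <- function(archetype, idx) {
  switch(archetype,
         full = rep(TRUE, length(idx)),
         downstream = idx > 0L,
         upstream = idx < 0L,
         none = rep(FALSE, length(idx)),
         stop("unknown archetype: ", archetype))
}

#' Plant the ground-truth nucleosome layout
#'
#' Stable nucleosomes sit at the equilibrium offsets (strand-oriented, the
#' +1 mean switched to 58/64 bp by TATA label) with per-gene Gaussian jitter
#' of SD \code{stable_jitter_sd}; which equilibrium positions are occupied
#' is governed by the gene's archetype. Dynamic nucleosomes sit at the
#' counterphase midpoints between adjacent equilibrium offsets for every
#' gene, with per-platform jitter SD \code{dynamic_jitter_sd} and
#' archetype-scaled presence probability applied at sampling time.
#'
#' @param annotation a \code{\linkS4class{GenomeAnnotation}} from
#'   \code{\link{makeAnnotation}}.
#' @param params the same \code{\link{architectureParams}}.
#' @return a \code{\linkS4class{TrueLayout}} with condition
#'   \code{"normal"}.
#' @export
makeArchitecture <- function(annotation, params = architectureParams()) {
  stopifnot(is(annotation, "GenomeAnnotation"),
            inherits(params, "ArchitectureParams"))
  eq <- params$equilibrium_offsets
  nUp <- sum(eq < 0L)
  idx <- c(seq.int(-nUp, -1L), seq_len(length(eq) - nUp))  # -3..-1, 1..5
  mid <- as.integer(round((eq[-1L] + eq[-length(eq)]) / 2))
  g <- genes(annotation)
  withSeed(deriveSeed(params$seed, "architecture"), {
    arch <- sample(names(params$archetype_fractions), nrow(g),
                   replace = TRUE, prob = params$archetype_fractions)
    presMult <- params$archetype_dynamic_mult[arch] *
      exp(stats::rnorm(nrow(g), 0, 0.2))
    pres <- pmin(0.98, pmax(0, params$dynamic_presence_prob * presMult))
    rows <- vector("list", nrow(g))
    plusIdx <- which(idx == 1L)
    for (i in seq_len(nrow(g))) {
      mean_off <- as.numeric(eq)
      mean_off[plusIdx] <- if (g$tata[i]) params$plus_one_offset_tata
                           else params$plus_one_offset_tatafree
      keep <- archetypeMask(arch[i], idx)
      sOff <- as.integer(round(mean_off +
                                 stats::rnorm(length(eq), 0,
                                              params$stable_jitter_sd)))
      sOff <- sOff[keep]
      sIdx <- idx[keep]
      # stable dyads never inside the planted NFR
      bad <- sOff > params$nfr_span[1L] & sOff < params$nfr_span[2L]
      sOff <- sOff[!bad]; sIdx <- sIdx[!bad]
      # dynamic nucleosomes occupy the counterphase midpoints where the
      # gene's stable array is locally absent: a 147 bp particle cannot
      # sit between two present stable neighbours only 166 bp apart
      dynKeep <- !keep[-length(keep)] & !keep[-1L]
      if (pres[i] == 0) dynKeep[] <- FALSE
      dMid <- mid[dynKeep]
      off <- c(sOff, dMid)
      if (!length(off)) next
      rows[[i]] <- data.frame(
        gene_id = g$gene_id[i], chrom = g$chrom[i], strand = g$strand[i],
        class = c(rep("stable", length(sOff)), rep("dynamic", length(dMid))),
        index = c(sIdx, rep(NA_integer_, length(dMid))),
        offset = as.integer(off),
        dyad = as.integer(orientPosition(off, g$tss[i], g$strand[i])),
        presence_prob = c(rep(1, length(sOff)), rep(pres[i], length(dMid))),
        stringsAsFactors = FALSE)
    }
    nuc <- do.call(rbind, rows)
    nuc <- nuc[order(nuc$gene_id, nuc$offset), , drop = FALSE]
    rownames(nuc) <- NULL
    gl <- data.frame(gene_id = g$gene_id, archetype = arch,
                     class = g$class, tata = g$tata,
                     stringsAsFactors = FALSE)
    new("TrueLayout", condition = "normal", nucleosomes = nuc, genes = gl,
        params = c(unclass(params),
                   list(chrom_sizes = chromSizes(annotation))))
  })
}

#' Describe one measurement platform
#'
#' @param name platform label.
#' @param positional_noise_sd Gaussian dyad noise SD (bp).
#' @param detection_rate probability a true nucleosome yields a call.
#' @param false_call_rate spurious calls per kb.
#' @param seed platform RNG seed.
#' @return a list of class \code{"PlatformSpec"}.
#' @export
platformSpec <- function(name, positional_noise_sd = 4,
                         detection_rate = 0.95, false_call_rate = 0.05,
                         seed = 1L) {
  if (detection_rate < 0 || detection_rate > 1)
    stop("detection_rate must lie in [0, 1]")
  if (positional_noise_sd < 0) stop("positional_noise_sd must be >= 0")
  if (false_call_rate < 0) stop("false_call_rate must be >= 0")
  structure(list(name = name,
                 positional_noise_sd = positional_noise_sd,
                 detection_rate = detection_rate,
                 false_call_rate = false_call_rate,
                 seed = as.integer(seed)),
            class = "PlatformSpec")
}

#' Six default platform specifications
#'
#' Emulates six independent genome-wide positioning studies of one shared
#' architecture: positional noise between 8 and 18 bp (cross-study dyad
#' discordance is far larger than any single study's stated resolution),
#' high detection rates, and a light sprinkle of false calls.
#'
#' @param seed base seed; each platform derives its own from it.
#' @return list of six \code{\link{platformSpec}} objects.
#' @export
defaultPlatformSpecs <- function(seed = 1L) {
  cfg <- list(c("arrayHMM", 12), c("seqH2AZ",  15), c("arrayFit", 18),
              c("seqSolexa", 8), c("seq454",   10), c("seqPyro", 10))
  lapply(seq_along(cfg), function(i)
    platformSpec(cfg[[i]][1L], as.numeric(cfg[[i]][2L]),
                 detection_rate = 0.95, false_call_rate = 0.05,
                 seed = deriveSeed(seed, paste0("platform", i))))
}

#' Sample platform-like call sets from a true layout
#'
#' Each platform observes the layout independently: stable calls keep their
#' true dyad plus platform positional noise and are thinned at
#' \code{detection_rate}; dynamic calls are additionally re-jittered with
#' the layout's \code{dynamic_jitter_sd} and thinned at their presence
#' probability (set \code{dynamicResample = FALSE} to treat dynamic
#' nucleosomes exactly like stable ones, the fully noiseless limit).
#' Poisson false calls are added at \code{false_call_rate} per kb.
#'
#' @param layout a \code{\linkS4class{TrueLayout}}.
#' @param specs list of \code{\link{platformSpec}} objects.
#' @param classes nucleosome classes to observe (default both).
#' @param dynamicResample logical; re-jitter and thin dynamic calls per
#'   platform (default TRUE).
#' @return list of \code{\linkS4class{NucleosomeCallSet}} objects, one per
#'   spec.
#' @export
samplePlatformCallsets <- function(layout, specs,
                                   classes = c("stable", "dynamic"),
                                   dynamicResample = TRUE) {
  stopifnot(is(layout, "TrueLayout"), length(specs) >= 1L)
  nuc <- layoutNucleosomes(layout)
  nuc <- nuc[nuc$class %in% classes, , drop = FALSE]
  sizes <- chromSizes(layout)
  fp <- layout@params$footprint
  half <- fp %/% 2L
  dynSd <- layout@params$dynamic_jitter_sd
  lapply(specs, function(spec) {
    stopifnot(inherits(spec, "PlatformSpec"))
    withSeed(spec$seed, {
      isDyn <- nuc$class == "dynamic" & dynamicResample
      keepP <- ifelse(isDyn, spec$detection_rate * nuc$presence_prob,
                      spec$detection_rate)
      keep <- stats::runif(nrow(nuc)) < keepP
      sd_i <- ifelse(isDyn,
                     sqrt(spec$positional_noise_sd^2 + dynSd^2),
                     spec$positional_noise_sd)
      dy <- nuc$dyad + round(stats::rnorm(nrow(nuc), 0, sd_i))
      df <- data.frame(chrom = nuc$chrom[keep],
                       dyad = as.integer(dy[keep]),
                       stringsAsFactors = FALSE)
      # spurious calls, uniform over each chromosome
      for (ch in names(sizes)) {
        nf <- stats::rpois(1L, spec$false_call_rate * sizes[[ch]] / 1000)
        if (nf > 0L)
          df <- rbind(df, data.frame(
            chrom = ch,
            dyad = as.integer(floor(stats::runif(nf, 0, sizes[[ch]]))),
            stringsAsFactors = FALSE))
      }
      lim <- sizes[df$chrom]
      df$dyad <- pmin(pmax(df$dyad, half), lim - (fp - half))
      df$start <- df$dyad - half
      df$end <- df$start + fp
      df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "dyad")]
      rownames(df) <- NULL
      new("NucleosomeCallSet", name = spec$name,
          condition = layout@condition, calls = df)
    })
  })
}

# Per-gene true occupancy of one class inside a strand-oriented window:
# stable nucleosomes count 1, dynamic ones their presence probability.
trueOccupancy <- function(layout, window, class) {
  nuc <- layoutNucleosomes(layout)
  nuc <- nuc[nuc$class == class & nuc$offset >= window[1L] &
               nuc$offset <= window[2L], , drop = FALSE]
  w <- if (class == "dynamic") nuc$presence_prob else rep(1, nrow(nuc))
  occ <- tapply(w, factor(nuc$gene_id, levels = genes(layout)$gene_id), sum,
                default = 0)
  as.numeric(occ)
}

#' Generate gene properties tied to the planted occupancy
#'
#' Each regulatory property is a linear response to the gene's true dynamic
#' occupancy (positive effect by default) and stable occupancy (negative
#' effect by default) inside stated promoter/coding windows, plus Gaussian
#' noise. The exact correlations implied by the realised occupancy vectors
#' are recorded in \code{attr(x, "planted")} so recovery can be checked.
#'
#' @param layout a \code{\linkS4class{TrueLayout}}.
#' @param beta_dyn effect of standardised dynamic occupancy (default +0.5).
#' @param beta_stab effect of standardised stable occupancy (default -0.5).
#' @param noise_sd residual SD (default 1).
#' @param dyn_window strand-oriented window (bp from TSS) in which dynamic
#'   occupancy drives properties (default 0..+640).
#' @param stab_window window in which stable occupancy drives properties
#'   (default -240..+560).
#' @param properties property column names to generate.
#' @param seed RNG seed.
#' @return data.frame \code{gene_id} + one column per property, with the
#'   planted correlation metadata in \code{attr(, "planted")}.
#' @export
makeGeneProperties <- function(layout, beta_dyn = 0.5, beta_stab = -0.5,
                               noise_sd = 1,
                               dyn_window = c(0L, 640L),
                               stab_window = c(-240L, 560L),
                               properties = c("transcription_rate",
                                              "mrna_abundance",
                                              "regulation_sensitivity",
                                              "h3_turnover",
                                              "expression_noise"),
                               seed = 1L) {
  stopifnot(is(layout, "TrueLayout"),
            is.finite(beta_dyn), is.finite(beta_stab), noise_sd >= 0)
  ids <- genes(layout)$gene_id
  d <- trueOccupancy(layout, dyn_window, "dynamic")
  s <- trueOccupancy(layout, stab_window, "stable")
  zd <- as.numeric(scale(d))
  zs <- as.numeric(scale(s))
  if (anyNA(zd)) zd <- rep(0, length(d))
  if (anyNA(zs)) zs <- rep(0, length(s))
  signal <- beta_dyn * zd + beta_stab * zs
  rho <- if (stats::sd(zd) > 0 && stats::sd(zs) > 0) stats::cor(zd, zs) else 0
  vTot <- stats::var(signal) + noise_sd^2
  planted <- list(
    beta_dyn = beta_dyn, beta_stab = beta_stab, noise_sd = noise_sd,
    dyn_window = dyn_window, stab_window = stab_window,
    r_dynamic = if (vTot > 0) (beta_dyn + beta_stab * rho) *
      stats::sd(zd)^2 / sqrt(vTot) else 0,
    r_stable = if (vTot > 0) (beta_stab + beta_dyn * rho) *
      stats::sd(zs)^2 / sqrt(vTot) else 0)
  withSeed(deriveSeed(seed, "properties"), {
    out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (pn in properties)
      out[[pn]] <- signal + stats::rnorm(length(ids), 0, noise_sd)
    attr(out, "planted") <- planted
    out
  })
}

#' Derive a heat-shock layout by sliding nucleosomes
#'
#' Activated genes' stable dyads move away from their equilibrium points,
#' outward from the TSS, by \code{shift_cap * |index| / max index} bp (up to
#' the cap at the most distal indices). Repressed genes' dyads move toward
#' their equilibrium points (deviation multiplied by
#' \code{converge_factor}). Basal genes receive small symmetric jitter.
#' A zero cap gates all movement: the layout is returned unchanged apart
#' from its condition label.
#'
#' @param layout a normal-condition \code{\linkS4class{TrueLayout}} with
#'   promoter classes assigned.
#' @param shift_cap maximal displacement (bp) at the most distal index
#'   (default 350).
#' @param converge_factor remaining fraction of the equilibrium deviation
#'   on repressed promoters (default 0.3).
#' @param basal_sd jitter SD for basal promoters (default 5 bp).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{TrueLayout}} with condition
#'   \code{"heat_shock"}.
#' @export
makeHeatShockLayout <- function(layout, shift_cap = 350,
                                converge_factor = 0.3, basal_sd = 5,
                                seed = 1L) {
  stopifnot(is(layout, "TrueLayout"), shift_cap >= 0)
  out <- layout
  out@condition <- "heat_shock"
  if (shift_cap == 0) return(out)
  nuc <- layoutNucleosomes(layout)
  g <- genes(layout)
  cls <- g$class[match(nuc$gene_id, g$gene_id)]
  eq <- layout@params$equilibrium_offsets
  nUp <- sum(eq < 0L)
  idxAll <- c(seq.int(-nUp, -1L), seq_len(length(eq) - nUp))
  eqOf <- stats::setNames(eq, idxAll)
  maxIdx <- max(abs(idxAll))
  withSeed(deriveSeed(seed, "heatshock"), {
    st <- nuc$class == "stable"
    off <- as.numeric(nuc$offset)
    act <- st & cls == "activated"
    mag <- shift_cap * abs(nuc$index) / maxIdx
    off[act] <- off[act] + sign(off[act]) * mag[act]
    rep_ <- st & cls == "repressed"
    eqv <- eqOf[as.character(nuc$index)]
    off[rep_] <- eqv[rep_] + converge_factor * (off[rep_] - eqv[rep_])
    bas <- st & cls == "basal"
    off[bas] <- off[bas] + stats::rnorm(sum(bas), 0, basal_sd)
    nuc$offset <- as.integer(round(off))
    # recompute genomic dyads from the (unchanged) anchors
    anchor <- nuc$dyad - ifelse(nuc$strand == "+", 1, -1) *
      as.integer(layoutNucleosomes(layout)$offset)
    nuc$dyad <- as.integer(orientPosition(nuc$offset, anchor, nuc$strand))
    out@nucleosomes <- nuc
    out
  })
}

#' Build an occupancy-ratio style track from calls
#'
#' Sums a footprint indicator centred on each call's dyad, optionally adding
#' Gaussian noise: a minimal emulation of continuous microarray occupancy
#' signal.
#'
#' @param callset a \code{\linkS4class{NucleosomeCallSet}}.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param footprint indicator width (bp, default 147).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed RNG seed (used only when \code{noise_sd > 0}).
#' @return a \code{\linkS4class{RealTrack}}.
#' @export
makeOccupancyTrack <- function(callset, chromSizes, footprint = 147L,
                               noise_sd = 0, seed = 1L) {
  stopifnot(is(callset, "NucleosomeCallSet"), footprint >= 1L)
  half <- footprint %/% 2L
  cl <- nucCalls(callset)
  vals <- lapply(stats::setNames(nm = names(chromSizes)), function(ch) {
    L <- chromSizes[[ch]]
    cc <- cl[cl$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) return(numeric(L))
    s <- pmax(cc$dyad - half, 0L)
    e <- pmin(s + footprint, L)
    cov <- IRanges::coverage(IRanges::IRanges(start = s + 1L, end = e),
                             width = L)
    as.numeric(cov)
  })
  if (noise_sd > 0)
    vals <- withSeed(deriveSeed(seed, "occupancy"),
                     lapply(vals, function(v)
                       v + stats::rnorm(length(v), 0, noise_sd)))
  new("RealTrack", values = vals, unit = "occupancy")
}

#' Simulate a complete cross-platform study
#'
#' One call generating everything downstream stages consume: annotation,
#' truth layout, six platform call sets with their binarised tracks, gene
#' properties, and a heat-shock condition with before/after call sets of
#' positioned (stable-class) nucleosomes for the sliding analysis.
#'
#' @param params an \code{\link{architectureParams}} object.
#' @param specs platform specifications (default
#'   \code{\link{defaultPlatformSpecs}} seeded from \code{params$seed}).
#' @param heatShock logical; also generate the heat-shock condition.
#' @return list with elements \code{annotation}, \code{layout},
#'   \code{callsets}, \code{tracks}, \code{properties}, and (if requested)
#'   \code{layoutHS}, \code{positionedBefore}, \code{positionedAfter}.
#' @export
simulateStudy <- function(params = architectureParams(),
                          specs = defaultPlatformSpecs(params$seed),
                          heatShock = TRUE) {
  anno <- makeAnnotation(params)
  layout <- makeArchitecture(anno, params)
  callsets <- samplePlatformCallsets(layout, specs)
  tracks <- lapply(callsets, binarizeCalls, chromSizes = chromSizes(anno),
                   footprint = params$footprint)
  names(tracks) <- vapply(callsets, function(x) x@name, character(1))
  props <- makeGeneProperties(layout, seed = deriveSeed(params$seed, "props"))
  out <- list(annotation = anno, layout = layout, callsets = callsets,
              tracks = tracks, properties = props, params = params)
  if (heatShock) {
    layoutHS <- makeHeatShockLayout(layout,
                                    seed = deriveSeed(params$seed, "hs"))
    specB <- platformSpec("positioned_normal", positional_noise_sd = 2,
                          detection_rate = 0.98, false_call_rate = 0,
                          seed = deriveSeed(params$seed, "posN"))
    specA <- platformSpec("positioned_heat", positional_noise_sd = 2,
                          detection_rate = 0.98, false_call_rate = 0,
                          seed = deriveSeed(params$seed, "posH"))
    out$layoutHS <- layoutHS
    out$positionedBefore <-
      samplePlatformCallsets(layout, list(specB), classes = "stable")[[1L]]
    out$positionedAfter <-
      samplePlatformCallsets(layoutHS, list(specA), classes = "stable")[[1L]]
  }
  out
}
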