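test_that("annotation construction honours placement and labelling contracts", {
  p <- smallParams(n_genes = 100L, seed = 1L)
  anno <- makeAnnotation(p)
  g <- genes(anno)
  expect_equal(nrow(g), 100L)
  # all pairwise TSS +/- 800 windows disjoint by construction
  tss <- sort(g$tss)
  expect_true(all(diff(tss) > 1600L))
  expect_true(all(g$tss - 800 >= 0 & g$tss + 800 < chromSizes(anno)["chrI"]))

  noTata <- makeAnnotation(smallParams(n_genes = 50L, tata_fraction = 0))
  expect_equal(sum(genes(noTata)$tata), 0L)

  expect_error(makeAnnotation(architectureParams(n_genes = 100L,
                                                 chrom_length = 10000L)),
               "too short")
})

test_that("generators are deterministic given the same params and seed", {
  p <- smallParams(n_genes = 30L, seed = 11L)
  a1 <- makeAnnotation(p); a2 <- makeAnnotation(p)
  expect_identical(genes(a1), genes(a2))
  l1 <- makeArchitecture(a1, p); l2 <- makeArchitecture(a2, p)
  expect_identical(layoutNucleosomes(l1), layoutNucleosomes(l2))
  specs <- defaultPlatformSpecs(11L)
  c1 <- samplePlatformCallsets(l1, specs)
  c2 <- samplePlatformCallsets(l2, specs)
  expect_identical(lapply(c1, nucCalls), lapply(c2, nucCalls))
  # different platform seeds give different call sets
  other <- samplePlatformCallsets(l1, defaultPlatformSpecs(12L))
  expect_false(identical(nucCalls(c1[[1L]]), nucCalls(other[[1L]])))
})

test_that("zero-jitter architecture puts +1 dyads exactly at class means", {
  p <- smallParams(n_genes = 60L, seed = 3L, stable_jitter_sd = 0,
                   tata_fraction = 0.5)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  nuc <- layoutNucleosomes(lay)
  g <- merge(nuc[nuc$class == "stable" & nuc$index == 1L, ],
             genes(anno)[, c("gene_id", "tata")], by = "gene_id")
  expect_true(all(g$offset[g$tata] == 58L))
  expect_true(all(g$offset[!g$tata] == 64L))
  # adjacent stable spacing matches the planted repeat away from the NFR
  full <- genes(lay)$gene_id[genes(lay)$archetype == "full"]
  one <- nuc[nuc$gene_id == full[1L] & nuc$class == "stable", ]
  spc <- diff(sort(one$offset))
  expect_true(all(spc[spc <= 200] %in% 161:167))
})

test_that("architecture respects NFR, ordering and archetype masks", {
  p <- smallParams(n_genes = 120L, seed = 5L)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  nuc <- layoutNucleosomes(lay)
  st <- nuc[nuc$class == "stable", ]
  expect_false(any(st$offset > p$nfr_span[1L] & st$offset < p$nfr_span[2L]))
  # along the genomic coordinate, dyads within a gene never collide
  ok <- vapply(split(nuc$dyad, nuc$gene_id),
               function(d) !is.unsorted(sort(d), strictly = TRUE),
               logical(1))
  expect_true(all(ok))
  arch <- genes(lay)
  noneGenes <- arch$gene_id[arch$archetype == "none"]
  expect_equal(sum(st$gene_id %in% noneGenes), 0L)
  fullGenes <- arch$gene_id[arch$archetype == "full"]
  expect_equal(sum(nuc$class == "dynamic" & nuc$gene_id %in% fullGenes), 0L)

  noDyn <- makeArchitecture(anno, smallParams(n_genes = 120L, seed = 5L,
                                              dynamic_presence_prob = 0))
  expect_equal(sum(layoutNucleosomes(noDyn)$class == "dynamic"), 0L)
})

test_that("platform sampling reproduces truth in the noiseless limit", {
  p <- smallParams(n_genes = 40L, seed = 9L)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  spec <- platformSpec("perfect", positional_noise_sd = 0,
                       detection_rate = 1, false_call_rate = 0, seed = 1L)
  cs <- samplePlatformCallsets(lay, list(spec), dynamicResample = FALSE)[[1L]]
  expect_equal(sort(nucCalls(cs)$dyad), sort(layoutNucleosomes(lay)$dyad))
  # generator self-consistency: binarized sampled calls == binarized truth
  truthCalls <- NucleosomeCallSet(
    data.frame(chrom = layoutNucleosomes(lay)$chrom,
               start = layoutNucleosomes(lay)$dyad - 73L,
               end = layoutNucleosomes(lay)$dyad + 74L))
  expect_identical(trackValues(binarizeCalls(cs, chromSizes(anno))),
                   trackValues(binarizeCalls(truthCalls, chromSizes(anno))))
})

test_that("detection thinning follows the binomial law", {
  p <- smallParams(n_genes = 1500L, seed = 13L, dynamic_presence_prob = 0)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  nTrue <- nrow(layoutNucleosomes(lay))
  expect_gt(nTrue, 4000L)
  spec <- platformSpec("thin", positional_noise_sd = 0,
                       detection_rate = 0.5, false_call_rate = 0, seed = 2L)
  got <- nrow(nucCalls(samplePlatformCallsets(lay, list(spec))[[1L]]))
  bounds <- qbinom(c(0.005, 0.995), nTrue, 0.5)
  expect_gte(got, bounds[1L])
  expect_lte(got, bounds[2L])
})

test_that("gene properties carry the planted associations", {
  p <- architectureParams(n_genes = 2000L, seed = 21L)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  props <- makeGeneProperties(lay, seed = 4L)
  planted <- attr(props, "planted")
  d <- nucensemble:::trueOccupancy(lay, planted$dyn_window, "dynamic")
  s <- nucensemble:::trueOccupancy(lay, planted$stab_window, "stable")
  for (pn in c("transcription_rate", "h3_turnover")) {
    expect_lt(abs(cor(props[[pn]], d) - planted$r_dynamic), 0.05)
    expect_lt(abs(cor(props[[pn]], s) - planted$r_stable), 0.05)
  }
  # noiseless, stable effect off: perfect rank correlation with dynamic
  pure <- makeGeneProperties(lay, beta_stab = 0, noise_sd = 0, seed = 4L)
  expect_equal(cor(pure$mrna_abundance, d, method = "spearman"), 1)
  # null case: no planted effect, correlation below the 99% null bound
  null <- makeGeneProperties(lay, beta_dyn = 0, beta_stab = 0, seed = 4L)
  expect_lt(abs(cor(null$expression_noise, d)), qnorm(0.995) / sqrt(2000))
})

test_that("heat-shock layout moves dyads as its promoter class dictates", {
  p <- smallParams(n_genes = 150L, seed = 17L)
  anno <- makeAnnotation(p)
  lay <- makeArchitecture(anno, p)
  same <- makeHeatShockLayout(lay, shift_cap = 0, seed = 1L)
  expect_identical(layoutNucleosomes(same), layoutNucleosomes(lay))
  expect_equal(same@condition, "heat_shock")

  hs <- makeHeatShockLayout(lay, seed = 1L)
  eqMap <- equilibriumIndexMap(p$equilibrium_offsets)
  before <- layoutNucleosomes(lay)
  after <- layoutNucleosomes(hs)
  cls <- genes(lay)$class[match(before$gene_id, genes(lay)$gene_id)]
  st <- before$class == "stable"
  dBefore <- abs(before$offset - eqMap[as.character(before$index)])
  dAfter <- abs(after$offset - eqMap[as.character(after$index)])
  act <- st & cls == "activated"
  expect_true(all(dAfter[act] > dBefore[act]))
  rep_ <- st & cls == "repressed"
  expect_lt(mean(dAfter[rep_]), mean(dBefore[rep_]))
})

test_that("occupancy tracks sum footprint indicators", {
  calls <- NucleosomeCallSet(data.frame(chrom = "chrI", start = 100L,
                                        end = 247L, dyad = 173L))
  tr <- makeOccupancyTrack(calls, c(chrI = 500L))
  v <- trackValues(tr, "chrI")
  expect_equal(sum(v == 1), 147L)
  expect_equal(which(v == 1) - 1L, 100:246)

  two <- NucleosomeCallSet(data.frame(chrom = "chrI",
                                      start = c(100L, 180L),
                                      end = c(247L, 327L),
                                      dyad = c(173L, 253L)))
  v2 <- trackValues(makeOccupancyTrack(two, c(chrI = 500L)), "chrI")
  expect_equal(max(v2), 2)
  expect_equal(sum(v2 == 2), 147L - 80L)

  none <- NucleosomeCallSet(data.frame(chrom = character(),
                                       start = integer(), end = integer()))
  expect_equal(sum(trackValues(makeOccupancyTrack(none, c(chrI = 500L)),
                               "chrI")), 0)
})
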