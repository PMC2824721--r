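test_that("feature matrix window handling matches the anchor machinery", {
  anno <- tinyAnnotation()
  flat <- RealTrack(list(chrI = runif(12000), chrII = runif(2000)))
  m <- occupancyFeatureMatrix(flat, anno, window = 1600L)
  expect_equal(ncol(m@signal), 1600L)
  expect_error(occupancyFeatureMatrix(flat, anno, window = 1601L), "even")
  # identical to the anchor-aligned matrix over the shared offsets
  a <- alignToAnchor(flat, anno, "TSS", 800L)
  shared <- match(m@offsets, a@offsets)
  expect_equal(m@signal, a@signal[, shared])
  # dropped-gene count equals the boundary violators (gC at flank 800)
  expect_equal(m@dropped, 1L)
})

test_that("k-means recovers structure deterministically", {
  set.seed(47)
  centres <- rbind(c(rep(1, 20), rep(0, 20)),
                   c(rep(0, 20), rep(1, 20)),
                   rep(0.5, 40),
                   rep(0, 40))
  x <- centres[rep(1:4, each = 50L), ] + matrix(rnorm(200 * 40, 0, 0.1),
                                                200L)
  gm <- new("GeneMatrix", signal = x, offsets = seq_len(40L),
            anchor = "TSS", geneIds = sprintf("g%03d", 1:200),
            dropped = 0L)
  c1 <- clusterGenes(gm, k = 4L, restarts = 5L, seed = 1L)
  c2 <- clusterGenes(gm, k = 4L, restarts = 5L, seed = 1L)
  expect_identical(c1$assignment, c2$assignment)
  expect_gte(ari(c1$assignment, rep(1:4, each = 50L)), 0.95)

  k1 <- clusterGenes(gm, k = 1L, restarts = 1L, seed = 1L)
  expect_equal(k1$inertia, sum(scale(x, scale = FALSE)^2))

  dup <- new("GeneMatrix", signal = matrix(1, 10L, 4L),
             offsets = 1:4, anchor = "TSS",
             geneIds = sprintf("g%d", 1:10), dropped = 0L)
  expect_error(clusterGenes(dup, k = 4L), "degenerate")
})

test_that("group frequency curves use the equal-subset window size", {
  set.seed(53)
  n <- 4792L
  assign <- setNames(sample(1:4, n, replace = TRUE), sprintf("g%04d", 1:n))
  prop <- setNames(rnorm(n), names(assign))
  fc <- groupFrequencyCurves(assign, prop)
  expect_equal(attr(fc, "windowGenes"), 209L)  # ceiling(4792 / 23)

  one <- setNames(rep(1L, 500L), sprintf("g%03d", 1:500))
  p1 <- setNames(rnorm(500L), names(one))
  flat <- groupFrequencyCurves(one, p1)
  expect_true(all(flat$percent == 100))

  # planted monotone association: group 2 occupies the upper property half
  grp <- setNames(rep(1:2, each = 1000L), sprintf("g%04d", 1:2000))
  pr <- setNames(c(rnorm(1000L, 0), rnorm(1000L, 3)), names(grp))
  mono <- groupFrequencyCurves(grp, pr)
  g2 <- mono[mono$group == 2L, ]
  expect_gt(cor(g2$mean_property, g2$percent, method = "spearman"), 0.9)
})

test_that("group density tests match the t oracle and stay calibrated", {
  x <- setNames(rep(c(0, 0), each = 100L) + rep(rnorm(100L), 2L),
                sprintf("g%03d", 1:200))
  same <- setNames(rep(1:2, each = 100L), names(x))
  x[same == 2L] <- x[same == 1L]
  r0 <- groupDensityTest(same, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  set.seed(59)
  y <- setNames(c(rnorm(200L), rnorm(200L, 5)), sprintf("g%03d", 1:400))
  shift <- setNames(rep(1:2, each = 200L), names(y))
  expect_lt(groupDensityTest(shift, y)$p, 1e-10)

  # permuted labels: p-values uniform (KS at alpha = 0.01, 500 reps)
  set.seed(61)
  z <- rnorm(60L)
  ps <- replicate(500L, {
    lab <- sample(rep(1:2, each = 30L))
    stats::t.test(z[lab == 1L], z[lab == 2L])$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LRC maps are exact, antisymmetric and calibrated under the null", {
  p <- smallParams(n_genes = 300L, seed = 67L)
  sim <- simulateStudy(p, heatShock = FALSE)
  xm <- xorMeanStack(sim$tracks)
  feat <- occupancyFeatureMatrix(xm, sim$annotation, 1600L)

  # property equal to one window's mean occupancy -> r = 1 at that cell
  w <- 200L; startCol <- 801L
  target <- rowMeans(feat@signal[, startCol:(startCol + w - 1L)])
  prop <- setNames(target, feat@geneIds)
  m <- lrcMap(feat, prop, widths = w, positionStep = 50L)
  cell <- m[m$centre == feat@offsets[startCol] + (w - 1) / 2, ]
  expect_equal(cell$r, 1)

  # negating the property negates every cell exactly
  set.seed(71)
  pr <- setNames(rnorm(length(feat@geneIds)), feat@geneIds)
  m1 <- lrcMap(feat, pr, widths = c(100L, 300L), positionStep = 100L)
  m2 <- lrcMap(feat, -pr, widths = c(100L, 300L), positionStep = 100L)
  expect_equal(m2$r, -m1$r)

  # independent property: fraction of |r| beyond the 1% critical value
  n <- length(feat@geneIds)
  rcrit <- qt(0.995, n - 2) / sqrt(n - 2 + qt(0.995, n - 2)^2)
  frac <- mean(abs(m1$r) > rcrit, na.rm = TRUE)
  expect_lt(frac, 0.05)
})

test_that("+1 distances follow the sign and border conventions", {
  anno <- tinyAnnotation()
  # stable dyads exactly at TSS+60 (strand-oriented) for gA and gB
  calls <- NucleosomeCallSet(data.frame(
    chrom = c("chrI", "chrI", "chrII"),
    start = c(3060L - 73L, 9000L - 60L - 73L, 500L - 73L),
    end = c(3060L + 74L, 9000L - 60L + 74L, 500L + 74L),
    dyad = c(3060L, 9000L - 60L, 500L)))
  res <- plusOneDistanceAnalysis(calls, anno, nBoot = 1L)
  d <- res$distances
  expect_equal(d$distance[d$gene_id == "gA"], -60)
  expect_equal(d$distance[d$gene_id == "gB"], -60)
  # dyad exactly at the TSS -> distance 0
  expect_equal(d$distance[d$gene_id == "gC"], 0)
  expect_equal(res$nExcluded, 0L)
  # TSS sits floor(147/2) - 60 = 13 bp inside the upstream border
  expect_equal(73 + d$distance[d$gene_id == "gA"], 13)

  # a gene with no downstream stable call is excluded and counted
  res2 <- plusOneDistanceAnalysis(
    NucleosomeCallSet(nucCalls(calls)[1:2, ]), anno, nBoot = 1L)
  expect_equal(res2$nExcluded, 1L)
})

test_that("TATA contrast recovers identical classes as a null difference", {
  p <- smallParams(n_genes = 200L, seed = 73L,
                   plus_one_offset_tata = 64L)  # both classes planted at 64
  sim <- simulateStudy(p, heatShock = FALSE)
  st <- logicalAndStack(sim$tracks)
  tc <- tataContrast(callsFromBinaryTrack(st), sim$annotation,
                     nBoot = 300L, seed = 73L)
  expect_gte(tc$difference$high, 0)
  expect_lte(tc$difference$low, 0)
  expect_lt(abs(tc$difference$estimate), 6)
  # degenerate bootstrap: a single resample collapses the interval
  tc1 <- tataContrast(callsFromBinaryTrack(st), sim$annotation,
                      nBoot = 1L, seed = 73L)
  expect_equal(tc1$difference$low, tc1$difference$estimate)

  oneClass <- sim$annotation
  oneClass@genes$tata <- FALSE
  expect_error(tataContrast(callsFromBinaryTrack(st), oneClass),
               "non-empty")
})
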