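test_that("logical AND equals the elementwise minimum (brute force)", {
  tracks <- randomBinaryTracks(n = 6L, len = 20L, seed = 1L)
  out <- trackValues(logicalAndStack(tracks), "chrI")
  brute <- Reduce(pmin, lapply(tracks, trackValues, chrom = "chrI"))
  expect_identical(out, as.integer(brute))

  same <- replicate(6L, tracks[[1L]], simplify = FALSE)
  expect_identical(trackValues(logicalAndStack(same), "chrI"),
                   trackValues(tracks[[1L]], "chrI"))

  zero <- c(tracks[1:5], list(BinaryTrack(integer(20L), chrom = "chrI")))
  expect_equal(sum(trackValues(logicalAndStack(zero), "chrI")), 0L)

  short <- BinaryTrack(integer(10L), chrom = "chrI")
  expect_error(logicalAndStack(list(tracks[[1L]], short)), "mismatch")
  expect_error(logicalAndStack(tracks[1L]), "at least 2")
})

test_that("xor mean matches the explicit all-pairs average", {
  # five datasets enumerate exactly choose(5,2) = 10 pairs
  five <- randomBinaryTracks(n = 5L, len = 30L, seed = 2L)
  xm5 <- xorMeanStack(five)
  expect_equal(attr(xm5, "n_pairs"), 10)

  # oracle: brute-force XOR over every pair, then arithmetic mean
  bruteXorMean <- function(tracks) {
    vs <- lapply(tracks, trackValues, chrom = "chrI")
    n <- length(vs)
    acc <- numeric(length(vs[[1L]]))
    cnt <- 0L
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      acc <- acc + as.integer(xor(vs[[a]] == 1L, vs[[b]] == 1L))
      cnt <- cnt + 1L
    }
    acc / cnt
  }
  expect_equal(trackValues(xm5, "chrI"), bruteXorMean(five))

  six <- randomBinaryTracks(n = 6L, len = 50L, seed = 3L)
  expect_equal(trackValues(xorMeanStack(six), "chrI"), bruteXorMean(six))

  # exhaustive 6-bit site patterns against the closed form k(n-k)/C(n,2)
  bits <- t(sapply(0:63, function(x) as.integer(intToBits(x)[1:6])))
  patTracks <- lapply(1:6, function(j) BinaryTrack(bits[, j], chrom = "chrI"))
  k <- rowSums(bits)
  expect_equal(trackValues(xorMeanStack(patTracks), "chrI"),
               k * (6 - k) / 15)
  expect_equal(trackValues(xorMeanStack(patTracks), "chrI"),
               bruteXorMean(patTracks))

  ident <- replicate(4L, five[[1L]], simplify = FALSE)
  expect_equal(sum(trackValues(xorMeanStack(ident), "chrI")), 0)
})

test_that("duplicating a track preserves agreement and the xor bound", {
  tracks <- randomBinaryTracks(n = 5L, len = 40L, seed = 4L)
  base <- trackValues(xorMeanStack(tracks), "chrI")
  more <- trackValues(xorMeanStack(c(tracks, tracks[1L])), "chrI")
  # sites of complete agreement remain at zero disagreement
  expect_true(all(more[base == 0] == 0))
  # and the mean disagreement never exceeds its binomial ceiling
  expect_true(all(base <= 5 / (2 * 4) + 1e-12))
  expect_true(all(more <= 6 / (2 * 5) + 1e-12))
})

test_that("binomial decomposition matches exhaustive enumeration", {
  six <- randomBinaryTracks(n = 6L, len = 50L, seed = 5L)
  bd <- bdidDecompose(six)
  pv <- trackValues(bd@p, "chrI")
  k <- rowSums(sapply(six, trackValues, chrom = "chrI"))
  expect_equal(pv, k / 6)

  # oracle: explicit C(n,k) p^k (1-p)^(n-k) via factorials
  for (kk in 0:6) {
    coef <- factorial(6) / (factorial(kk) * factorial(6 - kk))
    expect_equal(trackValues(bd@profiles[[paste0("k", kk)]], "chrI"),
                 coef * pv^kk * (1 - pv)^(6 - kk))
  }
  # conservation at machine precision
  tot <- Reduce(`+`, lapply(bd@profiles, trackValues, chrom = "chrI"))
  expect_lt(max(abs(tot - 1)), 1e-12)
  # P{X=n} = p^n; degenerate distribution at p = 1
  expect_equal(trackValues(bd@profiles$k6, "chrI"), pv^6)
  ones <- replicate(6L, BinaryTrack(rep(1L, 5L), chrom = "chrI"),
                    simplify = FALSE)
  bd1 <- bdidDecompose(ones)
  expect_equal(trackValues(bd1@profiles$k6, "chrI"), rep(1, 5))
  expect_equal(trackValues(bd1@profiles$k3, "chrI"), rep(0, 5))
  # direct worked values: p = 0.5, k = 3 -> 20 * 0.5^6 = 0.3125
  half <- lapply(1:6, function(j)
    BinaryTrack(as.integer(j <= 3L), chrom = "chrI"))
  expect_equal(trackValues(bdidDecompose(half)@profiles$k3, "chrI"), 0.3125)

  expect_equal(bd@groups,
               c("NFR", rep("dynamic", 4L), "stable", "stable"))
  grp <- bdidGroupTrack(bd, "stable")
  expect_equal(trackValues(grp, "chrI"),
               trackValues(bd@profiles$k5, "chrI") +
                 trackValues(bd@profiles$k6, "chrI"))
})

test_that("stable/dynamic linkage ties the operators together", {
  six <- randomBinaryTracks(n = 6L, len = 80L, seed = 6L)
  st <- trackValues(logicalAndStack(six), "chrI")
  xm <- trackValues(xorMeanStack(six), "chrI")
  pv <- trackValues(bdidDecompose(six)@p, "chrI")
  expect_identical(st == 1L, pv == 1)
  expect_identical(xm == 0, pv %in% c(0, 1))
})

test_that("dataset correlations behave at the extremes", {
  set.seed(7)
  v <- as.integer(runif(400) < 0.4)
  a <- BinaryTrack(v, chrom = "chrI")
  b <- BinaryTrack(1L - v, chrom = "chrI")
  rep1 <- datasetCorrelations(list(x = a, y = a))[["genome"]]
  expect_equal(rep1$r["x", "y"], 1)
  rep2 <- datasetCorrelations(list(x = a, y = b))[["genome"]]
  expect_equal(rep2$r["x", "y"], -1)
  # constant track flagged NA, excluded from the mean
  flat <- BinaryTrack(rep(1L, 400L), chrom = "chrI")
  rep3 <- datasetCorrelations(list(x = a, y = b, z = flat))[["genome"]]
  expect_true(is.na(rep3$r["x", "z"]))
  expect_equal(rep3$mean_r, -1)
  expect_error(datasetCorrelations(list(a, b), regions = "exon"), "unknown")
})

test_that("gene-region correlations are strand-oriented", {
  anno <- tinyAnnotation()
  # plant a signal upstream of each TSS (strand-aware) in track a only
  va <- integer(12000L); vb <- integer(12000L)
  va[(3000 - 400):(3000 - 1) + 1L] <- 1L          # gA promoter (+)
  va[(9000 + 1):(9000 + 400) + 1L] <- 1L          # gB promoter (-)
  set.seed(8)
  noise <- as.integer(runif(12000L) < 0.5)
  a <- list(chrI = va, chrII = integer(2000L))
  b <- list(chrI = as.integer(va | noise), chrII = integer(2000L))
  repP <- datasetCorrelations(list(x = BinaryTrack(a), y = BinaryTrack(b)),
                              annotation = anno,
                              regions = "promoter")[["promoter"]]
  # promoter segments of both strands consist of the planted ones in x
  expect_gt(repP$r["x", "y"], 0.4)
})

test_that("occupancy pair decomposition matches the 2x2 eigenstructure", {
  set.seed(9)
  z <- rnorm(500)
  a <- RealTrack(z, chrom = "chrI")
  expect_error(decomposeOccupancyPair(a, RealTrack(rep(1, 500),
                                                   chrom = "chrI")),
               "zero-variance")

  # b = a: independent component identically 0
  d1 <- decomposeOccupancyPair(a, a)
  expect_lt(max(abs(trackValues(d1$independent, "chrI"))), 1e-10)
  # b = -a: common component identically 0 under centering
  d2 <- decomposeOccupancyPair(a, RealTrack(-z, chrom = "chrI"))
  expect_lt(max(abs(trackValues(d2$common, "chrI"))), 1e-10)

  # closed form: standardised pair always has eigenvectors (1,1)/sqrt(2)
  # and (1,-1)/sqrt(2); common must equal (za+zb)/sqrt(2)
  w <- rnorm(500)
  bmix <- RealTrack(0.8 * z + 0.6 * w, chrom = "chrI")
  d3 <- decomposeOccupancyPair(a, bmix)
  za <- as.numeric(scale(z))
  zb <- as.numeric(scale(0.8 * z + 0.6 * w))
  expect_equal(abs(trackValues(d3$common, "chrI")), abs((za + zb) / sqrt(2)),
               tolerance = 1e-8)
  expect_equal(abs(trackValues(d3$independent, "chrI")),
               abs((za - zb) / sqrt(2)), tolerance = 1e-8)
  expect_gt(d3$eigenvalues[1L], d3$eigenvalues[2L])
})
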