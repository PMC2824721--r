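test_that("ordinal index assignment follows the one-by-one search", {
  anno <- tinyAnnotation()
  # gA (+, tss 3000): dyads at offsets -200, 60, 225
  calls <- NucleosomeCallSet(data.frame(
    chrom = "chrI",
    start = c(2800L, 3060L, 3225L) - 73L,
    end = c(2800L, 3060L, 3225L) + 74L,
    dyad = c(2800L, 3060L, 3225L)))
  idx <- indexNucleosomes(calls, GenomeAnnotation(genes(anno)[1L, ],
                                                  chromSizes(anno)))
  expect_equal(idx$index, c(1L, 2L, -1L))
  expect_equal(idx$offset, c(60, 225, -200))

  # minus-strand twin with mirrored genomic dyads gives the same table
  gB <- GenomeAnnotation(genes(anno)[2L, ], chromSizes(anno))
  mirrored <- NucleosomeCallSet(data.frame(
    chrom = "chrI",
    start = c(9200L, 8940L, 8775L) - 73L,
    end = c(9200L, 8940L, 8775L) + 74L,
    dyad = c(9200L, 8940L, 8775L)))
  idxB <- indexNucleosomes(mirrored, gB)
  expect_equal(idxB$index, idx$index)
  expect_equal(idxB$offset, idx$offset)

  # only downstream calls -> only positive indices
  dn <- NucleosomeCallSet(nucCalls(calls)[2:3, ])
  idxD <- indexNucleosomes(dn, GenomeAnnotation(genes(anno)[1L, ],
                                                chromSizes(anno)))
  expect_true(all(idxD$index > 0L))

  # calls beyond the +5/-3 range do not perturb assignment
  far <- rbind(nucCalls(calls),
               data.frame(chrom = "chrI", start = 4400L, end = 4547L,
                          dyad = 4473L))  # offset +1473 > maxOffset
  idxF <- indexNucleosomes(NucleosomeCallSet(far),
                           GenomeAnnotation(genes(anno)[1L, ],
                                            chromSizes(anno)))
  expect_equal(idxF$offset, idx$offset)
})

test_that("displacement summaries are zero at identity and flag singletons", {
  anno <- tinyAnnotation()
  calls <- NucleosomeCallSet(data.frame(
    chrom = "chrI", start = c(3060L, 3225L) - 73L,
    end = c(3060L, 3225L) + 74L, dyad = c(3060L, 3225L)))
  idx <- indexNucleosomes(calls, GenomeAnnotation(genes(anno)[1L, ],
                                                  chromSizes(anno)))
  same <- displacementByIndex(idx, idx, nBoot = 50L, seed = 1L)
  expect_true(all(same$mean_abs_displacement == 0))
  expect_true(all(same$degenerate))
})

test_that("kernel densities integrate to one and resolve modes", {
  d <- dyadKernelDensity(rep(60, 50), bandwidth = 10)
  expect_lt(abs(d$offset[which.max(d$density)] - 60), 2)
  step <- d$offset[2L] - d$offset[1L]
  expect_lt(abs(sum(d$density) * step - 1), 0.01)

  mix <- dyadKernelDensity(c(rnorm(500, -200, 5), rnorm(500, 200, 5)),
                           bandwidth = 15)
  dens <- mix$density
  locmax <- which(diff(sign(diff(dens))) < 0) + 1L
  modes <- mix$offset[locmax[order(-dens[locmax])][1:2]]
  expect_lt(max(abs(sort(modes) - c(-200, 200))), 15 / 2 + 3)
  expect_error(dyadKernelDensity(60), "at least 2")
})

test_that("convergence labelling is tie-aware and antisymmetric", {
  mkIdx <- function(offsets, cond = "normal") {
    out <- data.frame(gene_id = rep(names(offsets),
                                    lengths(offsets)),
                      index = unlist(lapply(offsets, seq_along),
                                     use.names = FALSE),
                      offset = unlist(offsets, use.names = FALSE))
    out$condition <- cond
    class(out) <- c("IndexedDyads", "data.frame")
    out
  }
  eq <- c(`1` = 60, `2` = 225)
  before <- mkIdx(list(g1 = c(80, 250), g2 = c(70, 240)))
  atEq <- mkIdx(list(g1 = c(60, 225), g2 = c(70, 240)), "heat_shock")
  conv <- equilibriumConvergence(before, atEq, eq)
  pg <- conv$perGene
  expect_equal(pg$pattern[pg$gene_id == "g1"], "convergent")
  expect_equal(pg$d_after[pg$gene_id == "g1"], 0)
  expect_equal(pg$pattern[pg$gene_id == "g2"], "neutral")

  away <- mkIdx(list(g1 = c(120, 300), g2 = c(40, 200)), "heat_shock")
  c1 <- equilibriumConvergence(before, away, eq)$perGene
  c2 <- equilibriumConvergence(away, before, eq)$perGene
  swap <- c(convergent = "divergent", divergent = "convergent",
            neutral = "neutral")
  expect_equal(unname(swap[c1$pattern]), c2$pattern)
})

test_that("pattern enrichment matches the hypergeometric oracle", {
  pat <- setNames(rep(c("convergent", "divergent"), each = 50L),
                  sprintf("g%03d", 1:100))
  cls <- setNames(rep(c("repressed", "activated"), each = 50L),
                  names(pat))
  res <- patternEnrichmentTest(pat, cls)
  expect_lt(res$p, 1e-10)
  # two-sided Fisher p for the diagonal table equals twice the
  # hypergeometric point mass at the observed extreme
  oracle <- 2 * dhyper(50, 50, 50, 50)
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # zero margin rejected with an explanatory error
  allConv <- setNames(rep("convergent", 100L), names(pat))
  expect_error(patternEnrichmentTest(allConv, cls), "zero margin")

  # independent labels: p uniform under permutation
  set.seed(79)
  ps <- replicate(500L, {
    shuffled <- setNames(sample(pat), names(pat))
    patternEnrichmentTest(shuffled, cls)$p
  })
  # Fisher p-values are discrete and conservative; check no excess of
  # small values rather than exact uniformity
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("bootstrap intervals are seeded, sane and CLT-sized", {
  cst <- bootstrapCI(rep(3.5, 20L), nBoot = 200L, seed = 1L)
  expect_equal(cst$low, 3.5)
  expect_equal(cst$high, 3.5)

  set.seed(83)
  x <- rnorm(100)
  b1 <- bootstrapCI(x, nBoot = 1000L, seed = 5L)
  b2 <- bootstrapCI(x, nBoot = 1000L, seed = 5L)
  expect_identical(b1, b2)
  width <- b1$high - b1$low
  expect_lt(abs(width - 2 * 1.96 / sqrt(100)) / (2 * 1.96 / sqrt(100)), 0.2)
  expect_true(b1$low <= b1$estimate && b1$estimate <= b1$high)
})
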