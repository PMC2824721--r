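# hand-built 3-gene annotation on two chromosomes: one plus-strand, one
# minus-strand twin, one gene close to the chromosome end
tinyAnnotation <- function() {
  GenomeAnnotation(
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = c("chrI", "chrI", "chrII"),
               strand = c("+", "-", "+"),
               tss = c(3000L, 9000L, 500L),
               tts = c(4200L, 7800L, 1700L),
               tata = c(TRUE, FALSE, FALSE),
               class = c("activated", "repressed", "basal"),
               stringsAsFactors = FALSE),
    chromSizes = c(chrI = 12000L, chrII = 2000L))
}

# binary track with ones at given 0-based positions
trackWithOnes <- function(positions, len = 12000L, chrom = "chrI") {
  v <- integer(len)
  v[positions + 1L] <- 1L
  BinaryTrack(v, chrom = chrom)
}

randomBinaryTracks <- function(n = 6L, len = 50L, seed = 1L, p = 0.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    BinaryTrack(as.integer(runif(len) < p), chrom = "chrI"))
}

# adjusted Rand index, direct from the pair-count formula
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- si * sj / np
  (sij - expected) / ((si + sj) / 2 - expected)
}

smallParams <- function(n_genes = 80L, seed = 7L, ...) {
  architectureParams(n_genes = n_genes, seed = seed, ...)
}
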