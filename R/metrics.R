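#' Per-gene measurability across datasets
#'
#' Measurability of a gene is the average Pearson correlation between all
#' C(n,2) pairs of binary datasets over the gene's TSS window (+/-flank).
#' Zero-variance pairs are excluded and \code{n_pairs} decremented; a gene
#' with no defined pair gets NA.
#'
#' @param tracks list of \code{\linkS4class{BinaryTrack}} objects (>= 2).
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param flank half-window around the TSS (bp, default 800).
#' @return data.frame with \code{gene_id}, \code{measurability},
#'   \code{n_pairs}.
#' @export
geneMeasurability <- function(tracks, annotation, flank = 800L) {
  checkTrackStack(tracks)
  mats <- lapply(tracks, function(tr)
    alignToAnchor(tr, annotation, "TSS", flank)@signal)
  ids <- rownames(mats[[1L]])
  n <- length(mats)
  G <- nrow(mats[[1L]])
  W <- ncol(mats[[1L]])
  mu <- lapply(mats, rowMeans)
  cmats <- lapply(seq_len(n), function(j) mats[[j]] - mu[[j]])
  ssd <- lapply(cmats, function(m) sqrt(rowSums(m * m)))
  rsum <- numeric(G)
  rcnt <- integer(G)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    denom <- ssd[[a]] * ssd[[b]]
    r <- rowSums(cmats[[a]] * cmats[[b]]) / denom
    ok <- denom > 0
    rsum[ok] <- rsum[ok] + r[ok]
    rcnt[ok] <- rcnt[ok] + 1L
  }
  data.frame(gene_id = ids,
             measurability = ifelse(rcnt > 0, rsum / rcnt, NA_real_),
             n_pairs = rcnt, stringsAsFactors = FALSE)
}

# energy ratio in dB with infinity sentinels
snrDb <- function(S, D) {
  ifelse(D > 0 & S > 0, 10 * log10(S / D),
         ifelse(D == 0 & S > 0, Inf, ifelse(S == 0 & D > 0, -Inf, NA_real_)))
}

asProfileSignal <- function(x) {
  if (is(x, "CompositeProfile")) return(list(signal = x@signal, offsets = x@offsets))
  if (is(x, "GeneMatrix")) return(list(signal = colMeans(x@signal), offsets = x@offsets))
  stop("need a CompositeProfile or GeneMatrix")
}

#' Positioning SNR along the promoter
#'
#' In a sliding window, S is the mean squared stable signal and D the mean
#' squared dynamic signal ("average energies"); the SNR is 10*log10(S/D)
#' in dB. Windows with zero dynamic energy yield +Inf (flagged), zero
#' stable energy -Inf.
#'
#' @param stable stable composite (\code{\linkS4class{CompositeProfile}} or
#'   \code{\linkS4class{GeneMatrix}}).
#' @param dynamic dynamic composite, same offsets.
#' @param window sliding window width (bp, default 200).
#' @param step window step (bp, default 1).
#' @return data.frame with \code{offset} (window centre), \code{S},
#'   \code{D}, \code{snr_db}.
#' @export
snrCurve <- function(stable, dynamic, window = 200L, step = 1L) {
  st <- asProfileSignal(stable)
  dy <- asProfileSignal(dynamic)
  if (!identical(st$offsets, dy$offsets))
    stop("stable and dynamic inputs cover different offsets")
  stopifnot(window >= 2L, step >= 1L)
  n <- length(st$signal)
  if (window > n) stop("window wider than the profile")
  cs <- cumsum(c(0, st$signal^2))
  cd <- cumsum(c(0, dy$signal^2))
  starts <- seq.int(1L, n - window + 1L, by = step)
  S <- (cs[starts + window] - cs[starts]) / window
  D <- (cd[starts + window] - cd[starts]) / window
  data.frame(offset = st$offsets[starts] + (window - 1L) / 2,
             S = S, D = D, snr_db = snrDb(S, D))
}

#' Single-window SNR of one gene
#'
#' The degenerate one-window case of \code{\link{snrCurve}}: energies over
#' the full aligned window.
#'
#' @param stableRow,dynamicRow numeric signal vectors of equal length.
#' @return SNR in dB (+/-Inf sentinels as in \code{\link{snrCurve}}).
#' @export
geneSnr <- function(stableRow, dynamicRow) {
  if (length(stableRow) != length(dynamicRow))
    stop("rows must have equal length")
  snrDb(mean(stableRow^2), mean(dynamicRow^2))
}

#' Per-gene SNR table
#'
#' @param stable,dynamic \code{\linkS4class{GeneMatrix}} objects over the
#'   same genes and offsets.
#' @return data.frame with \code{gene_id} and \code{snr_db}.
#' @export
geneSnrTable <- function(stable, dynamic) {
  stopifnot(is(stable, "GeneMatrix"), is(dynamic, "GeneMatrix"))
  common <- intersect(stable@geneIds, dynamic@geneIds)
  s <- stable@signal[match(common, stable@geneIds), , drop = FALSE]
  d <- dynamic@signal[match(common, dynamic@geneIds), , drop = FALSE]
  data.frame(gene_id = common,
             snr_db = snrDb(rowMeans(s^2), rowMeans(d^2)),
             stringsAsFactors = FALSE)
}
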