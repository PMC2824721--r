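# shared extractor: per-gene signal at arbitrary strand-oriented offsets
geneSignalMatrix <- function(track, annotation, anchor, offsets) {
  g <- genes(annotation)
  lens <- chromSizes(annotation)
  anchorPos <- if (anchor == "TSS") g$tss else g$tts
  keep <- logical(nrow(g))
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    pos <- orientPosition(offsets, anchorPos[i], g$strand[i])
    if (min(pos) < 0L || max(pos) >= lens[[g$chrom[i]]]) next
    rows[[i]] <- as.numeric(trackValues(track, g$chrom[i])[pos + 1L])
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no usable genes: every window leaves the chromosome")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- g$gene_id[keep]
  new("GeneMatrix", signal = m, offsets = as.integer(offsets),
      anchor = anchor, geneIds = g$gene_id[keep],
      dropped = sum(!keep))
}

#' Align a track around gene anchors
#'
#' Extracts the signal in \code{[-flank, +flank]} around each gene's TSS or
#' TTS, strand-oriented so negative offsets are upstream. Genes whose
#' window extends beyond the chromosome are dropped and counted.
#'
#' @param track a \code{\linkS4class{BinaryTrack}} or
#'   \code{\linkS4class{RealTrack}}.
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param anchor \code{"TSS"} (default) or \code{"TTS"}.
#' @param flank half-window (bp, default 800).
#' @return a \code{\linkS4class{GeneMatrix}} with 2*flank+1 columns.
#' @export
alignToAnchor <- function(track, annotation, anchor = c("TSS", "TTS"),
                          flank = 800L) {
  anchor <- match.arg(anchor)
  stopifnot(flank >= 1L)
  geneSignalMatrix(track, annotation, anchor, seq.int(-flank, flank))
}

#' Average a gene matrix into a composite profile
#'
#' @param m a \code{\linkS4class{GeneMatrix}}.
#' @return a \code{\linkS4class{CompositeProfile}} of column means.
#' @export
compositeProfile <- function(m) {
  stopifnot(is(m, "GeneMatrix"))
  if (!nrow(m@signal)) stop("empty gene matrix")
  new("CompositeProfile", offsets = m@offsets,
      signal = colMeans(m@signal), nGenes = nrow(m@signal),
      anchor = m@anchor)
}

# moving-average smoothing preserving length; edges use shrinking windows
smoothProfile <- function(x, window) {
  if (window <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- window %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect peaks in a composite profile
#'
#' The profile is smoothed with a centred moving average and local maxima
#' are collected. Adjacent maxima separated only by a shallow dip (valley
#' above \code{mergeValleyRatio} of the lower maximum, heights measured
#' from the profile minimum) are merged: consensus profiles built from
#' binary tracks have flat, slightly double-humped peak tops (footprint
#' intersections), and the humps of one peak must not be counted twice.
#' Merged maxima below \code{minProminence} are discarded, maxima closer
#' than \code{minSeparation} greedily suppressed keeping the higher one
#' (ties toward the smaller |offset|), and every surviving peak is
#' reported at the centroid of its region above half height between the
#' flanking valleys, which places a flat-topped peak at its centre.
#'
#' @param p a \code{\linkS4class{CompositeProfile}}.
#' @param smoothWindow moving-average width (bp, odd; default 31).
#' @param minSeparation minimal distance between reported peaks (bp,
#'   default 100).
#' @param minProminence minimal prominence (height above the higher
#'   flanking valley); default 12\% of the smoothed profile's range.
#' @param mergeValleyRatio dips shallower than this fraction of the lower
#'   neighbouring maximum are treated as one peak (default 0.8).
#' @return a \code{\linkS4class{PeakSet}} (possibly empty).
#' @export
detectPeaks <- function(p, smoothWindow = 31L, minSeparation = 100L,
                        minProminence = NULL, mergeValleyRatio = 0.8) {
  stopifnot(is(p, "CompositeProfile"), minSeparation >= 1L)
  if (smoothWindow %% 2L == 0L) stop("smoothWindow must be odd")
  s <- smoothProfile(p@signal, smoothWindow)
  n <- length(s)
  rng <- diff(range(s))
  if (is.null(minProminence)) minProminence <- 0.12 * rng
  params <- list(smoothWindow = smoothWindow,
                 minSeparation = minSeparation,
                 minProminence = minProminence,
                 mergeValleyRatio = mergeValleyRatio)
  empty <- new("PeakSet", offsets = numeric(0), heights = numeric(0),
               params = params)
  if (rng == 0) return(empty)
  base <- min(s)
  cand <- which(diff(sign(diff(s))) < 0) + 1L  # strict local maxima
  if (!length(cand)) return(empty)
  # merge across shallow dips
  merged <- cand[1L]
  for (i in cand[-1L]) {
    prev <- merged[length(merged)]
    valley <- min(s[prev:i])
    lower <- min(s[prev], s[i])
    if (valley - base > mergeValleyRatio * (lower - base)) {
      if (s[i] > s[prev]) merged[length(merged)] <- i
    } else {
      merged <- c(merged, i)
    }
  }
  cand <- merged
  # prominence: height above the higher of the two flanking valleys,
  # valleys bounded by the adjacent retained maxima (or profile ends)
  bounds <- c(1L, cand, n)
  prom <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    vl <- min(s[bounds[j]:i])
    vr <- min(s[i:bounds[j + 2L]])
    s[i] - max(vl, vr)
  }, numeric(1))
  keep <- prom >= minProminence
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  # positional refinement first, shape-aware. Flat-topped peaks (footprint
  # intersections in binary consensus profiles) are located at the
  # midpoint of their two flank half-height crossings, each flank measured
  # against its own valley, which recovers the dyad no matter how unequal
  # the valleys are. Narrow rounded peaks are located at the midpoint of
  # the contiguous region above valley + 50% prominence (valley = higher
  # flanking minimum), which is unbiased for a symmetric bump between
  # unequal valleys. A peak counts as flat-topped when its top region
  # (within 15% of prominence below the apex) is at least 50 bp wide.
  bounds <- c(1L, cand, n)
  refined <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    lo <- bounds[j]; hi <- bounds[j + 2L]
    vl <- min(s[lo:i])
    vr <- min(s[i:hi])
    pm <- s[i] - max(vl, vr)
    topThr <- s[i] - 0.15 * pm
    tl <- i; while (tl > lo && s[tl - 1L] >= topThr) tl <- tl - 1L
    tr_ <- i; while (tr_ < hi && s[tr_ + 1L] >= topThr) tr_ <- tr_ + 1L
    if (tr_ - tl >= 50L) {
      cross <- function(valley, dir) {
        thr <- (s[i] + valley) / 2
        k <- i
        while (k + dir >= lo && k + dir <= hi && s[k + dir] >= thr)
          k <- k + dir
        kn <- k + dir
        if (kn < 1L || kn > n || s[k] == s[kn])
          return(as.numeric(p@offsets[k]))
        as.numeric(p@offsets[k]) + dir * (s[k] - thr) / (s[k] - s[kn])
      }
      (cross(vl, -1L) + cross(vr, 1L)) / 2
    } else {
      thr <- max(vl, vr) + 0.5 * pm
      l <- i; while (l > 1L && s[l - 1L] >= thr) l <- l - 1L
      r <- i; while (r < n && s[r + 1L] >= thr) r <- r + 1L
      (as.numeric(p@offsets[l]) + as.numeric(p@offsets[r])) / 2
    }
  }, numeric(1))
  ht <- s[cand]
  ord <- order(-ht, abs(refined))
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(refined[kept] - refined[i]) >= minSeparation))
      kept <- c(kept, i)
  }
  kept <- kept[order(refined[kept])]
  new("PeakSet", offsets = refined[kept], heights = ht[kept],
      params = params)
}

#' Spacing between successive peaks
#'
#' Successive peak-to-peak distances; differences larger than
#' \code{gapThreshold} (the NFR-spanning gap) are excluded from the mean
#' and reported separately.
#'
#' @param peaks a \code{\linkS4class{PeakSet}} or numeric vector of peak
#'   offsets.
#' @param gapThreshold largest spacing counted as an array-internal repeat
#'   (bp, default 200).
#' @return list with \code{spacings}, \code{meanSpacing} and \code{gaps}.
#' @export
peakSpacing <- function(peaks, gapThreshold = 200) {
  off <- if (is(peaks, "PeakSet")) peakOffsets(peaks) else as.numeric(peaks)
  if (length(off) < 2L) stop("need at least 2 peaks")
  d <- diff(sort(off))
  keep <- d <= gapThreshold
  list(spacings = d[keep],
       meanSpacing = if (any(keep)) mean(d[keep]) else NA_real_,
       gaps = d[!keep])
}
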