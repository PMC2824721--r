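#' Percentile bootstrap confidence interval
#'
#' @param values numeric sample (>= 1 value).
#' @param statistic summary function (default \code{mean}).
#' @param nBoot resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with \code{estimate}, \code{low}, \code{high},
#'   \code{nBoot}.
#' @export
bootstrapCI <- function(values, statistic = mean, nBoot = 1000L,
                        level = 0.95, seed = 1L) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("need at least 1 value")
  est <- statistic(values)
  if (nBoot <= 1L || length(values) == 1L)
    return(list(estimate = est, low = est, high = est, nBoot = nBoot))
  bs <- withSeed(seed, vapply(seq_len(nBoot), function(i)
    statistic(sample(values, replace = TRUE)), numeric(1)))
  a <- (1 - level) / 2
  list(estimate = est,
       low = unname(stats::quantile(bs, a)),
       high = unname(stats::quantile(bs, 1 - a)),
       nBoot = nBoot)
}

#' Assign ordinal indices to nucleosomes around each TSS
#'
#' Call dyads are converted to strand-oriented offsets from the TSS;
#' downstream dyads (offset >= 0) are numbered +1, +2, ... in increasing
#' offset, upstream dyads -1, -2, ... in decreasing offset. Indices beyond
#' \code{-maxUp}/\code{+maxDown} are discarded.
#'
#' @param calls a \code{\linkS4class{NucleosomeCallSet}}.
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param maxOffset search radius around the TSS (bp, default 1200).
#' @param maxUp largest upstream index kept (default 3).
#' @param maxDown largest downstream index kept (default 5).
#' @return data.frame of class \code{"IndexedDyads"} with \code{gene_id},
#'   \code{index}, \code{offset}, \code{condition}.
#' @export
indexNucleosomes <- function(calls, annotation, maxOffset = 1200L,
                             maxUp = 3L, maxDown = 5L) {
  offs <- callOffsetsByGene(calls, annotation, maxOffset = maxOffset)
  rows <- list()
  for (gid in names(offs)) {
    o <- offs[[gid]]
    if (!length(o)) next
    dn <- sort(o[o >= 0])
    up <- sort(o[o < 0], decreasing = TRUE)
    idx <- c(seq_along(dn), -seq_along(up))
    off <- c(dn, up)
    keep <- idx >= -maxUp & idx <= maxDown
    if (any(keep))
      rows[[gid]] <- data.frame(gene_id = gid, index = idx[keep],
                                offset = off[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene_id = character(), index = integer(),
                         offset = numeric())
  rownames(out) <- NULL
  out$condition <- calls@condition
  class(out) <- c("IndexedDyads", "data.frame")
  out
}

# merge two IndexedDyads tables on (gene, index)
pairDyads <- function(before, after) {
  m <- merge(as.data.frame(before)[, c("gene_id", "index", "offset")],
             as.data.frame(after)[, c("gene_id", "index", "offset")],
             by = c("gene_id", "index"), suffixes = c("_before", "_after"))
  m$delta <- m$offset_after - m$offset_before
  m
}

#' Mean absolute dyad displacement per nucleosome index
#'
#' Pairs nucleosomes across conditions by (gene, ordinal index), computes
#' the signed displacement after - before, and summarises |displacement|
#' per index for all promoters and per promoter class, with percentile
#' bootstrap intervals. Genes missing either condition at an index are
#' excluded for that index.
#'
#' @param before,after \code{"IndexedDyads"} tables from
#'   \code{\link{indexNucleosomes}}.
#' @param classes named character vector gene_id -> promoter class.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return data.frame with \code{index}, \code{class}, \code{n},
#'   \code{mean_abs_displacement}, \code{low}, \code{high},
#'   \code{mean_signed}; single-observation cells have \code{low = high =}
#'   the estimate and are flagged in \code{degenerate}.
#' @export
displacementByIndex <- function(before, after, classes = NULL,
                                nBoot = 1000L, seed = 1L) {
  m <- pairDyads(before, after)
  if (!nrow(m)) stop("no (gene, index) pairs shared between conditions")
  m$class <- if (is.null(classes)) "all"
             else as.character(classes[m$gene_id])
  rows <- list()
  classLevels <- unique(c("all", stats::na.omit(unique(m$class))))
  for (cl in classLevels) {
    sub <- if (cl == "all") m else m[!is.na(m$class) & m$class == cl, ]
    for (ix in sort(unique(sub$index))) {
      v <- abs(sub$delta[sub$index == ix])
      if (!length(v)) next
      ci <- bootstrapCI(v, nBoot = nBoot,
                        seed = deriveSeed(seed, paste(cl, ix)))
      rows[[length(rows) + 1L]] <-
        data.frame(index = ix, class = cl, n = length(v),
                   mean_abs_displacement = ci$estimate,
                   low = ci$low, high = ci$high,
                   mean_signed = mean(sub$delta[sub$index == ix]),
                   degenerate = length(v) == 1L)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Kernel density of dyad offsets for one nucleosome index
#'
#' Gaussian kernel density on the offset axis, normalised so that it
#' integrates to 1 over the evaluation range.
#'
#' @param offsets dyad offsets (bp); >= 2 values.
#' @param bandwidth kernel SD (bp, default 15).
#' @param from,to evaluation range (default -800..800).
#' @param n evaluation points (default 1601).
#' @return data.frame with \code{offset} and \code{density}.
#' @export
dyadKernelDensity <- function(offsets, bandwidth = 15, from = -800,
                              to = 800, n = 1601L) {
  if (length(offsets) < 2L) stop("need at least 2 observations")
  d <- stats::density(offsets, bw = bandwidth, from = from, to = to, n = n)
  data.frame(offset = d$x, density = d$y)
}

#' Convergence/divergence of nucleosomes relative to equilibrium points
#'
#' Each ordinal index is mapped to its equilibrium offset; per gene the
#' mean |dyad - equilibrium| over its observed indices is compared between
#' conditions. A gene converges when the after-distance is smaller,
#' diverges when larger, and is neutral on a tie. Per-class and per-index
#' summaries accompany the per-gene labels.
#'
#' @param before,after \code{"IndexedDyads"} tables.
#' @param equilibriumOffsets named numeric vector mapping index (as
#'   character, e.g. \code{"-1"}, \code{"2"}) to its equilibrium offset.
#' @param classes named character vector gene_id -> promoter class.
#' @return list with \code{perGene} (gene, class, distance before/after,
#'   pattern) and \code{byIndex} (class x index mean distances).
#' @export
equilibriumConvergence <- function(before, after, equilibriumOffsets,
                                   classes = NULL) {
  m <- pairDyads(before, after)
  if (!nrow(m)) stop("no (gene, index) pairs shared between conditions")
  eq <- equilibriumOffsets[as.character(m$index)]
  m <- m[!is.na(eq), , drop = FALSE]
  eq <- eq[!is.na(eq)]
  m$d_before <- abs(m$offset_before - eq)
  m$d_after <- abs(m$offset_after - eq)
  agg <- stats::aggregate(cbind(d_before, d_after) ~ gene_id, data = m, FUN = mean)
  agg$pattern <- ifelse(agg$d_after < agg$d_before, "convergent",
                        ifelse(agg$d_after > agg$d_before, "divergent",
                               "neutral"))
  agg$class <- if (is.null(classes)) NA_character_
               else as.character(classes[agg$gene_id])
  m$class <- if (is.null(classes)) "all" else as.character(classes[m$gene_id])
  byIndex <- stats::aggregate(cbind(d_before, d_after) ~ class + index,
                              data = m[!is.na(m$class), ], FUN = mean)
  byIndex$pattern <- ifelse(byIndex$d_after < byIndex$d_before,
                            "convergent",
                            ifelse(byIndex$d_after > byIndex$d_before,
                                   "divergent", "neutral"))
  list(perGene = agg, byIndex = byIndex)
}

#' Enrichment of sliding patterns in promoter classes
#'
#' Contingency test of pattern (convergent/divergent) against promoter
#' class: Fisher's exact test for a 2x2 table, chi-squared otherwise.
#' Tables with a zero margin are rejected.
#'
#' @param patterns named character vector gene_id -> pattern (neutral
#'   entries are dropped).
#' @param classes named character vector gene_id -> promoter class.
#' @param keepClasses classes entering the table (default activated and
#'   repressed).
#' @return list with \code{table}, \code{p}, \code{method} and (2x2)
#'   \code{odds_ratio}.
#' @export
patternEnrichmentTest <- function(patterns, classes,
                                  keepClasses = c("activated", "repressed")) {
  ids <- intersect(names(patterns), names(classes))
  pat <- patterns[ids]
  cls <- classes[ids]
  keep <- pat %in% c("convergent", "divergent") & cls %in% keepClasses
  tab <- table(pattern = factor(pat[keep],
                                levels = c("convergent", "divergent")),
               class = factor(cls[keep], levels = keepClasses))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("contingency table has a zero margin; cannot test enrichment ",
         "(every pattern and class must be observed at least once)")
  if (all(dim(tab) == c(2L, 2L))) {
    ft <- stats::fisher.test(tab)
    list(table = tab, p = ft$p.value, method = "fisher",
         odds_ratio = unname(ft$estimate))
  } else {
    ct <- stats::chisq.test(tab)
    list(table = tab, p = ct$p.value, method = "chisq", odds_ratio = NA_real_)
  }
}

#' Map ordinal indices to equilibrium offsets
#'
#' Builds the index -> offset lookup used by
#' \code{\link{equilibriumConvergence}} from an ascending offset vector
#' (negative offsets become -1 closest to the TSS, positive +1 upward).
#'
#' @param equilibriumOffsets ascending offsets (bp relative to TSS).
#' @return named numeric vector keyed by index.
#' @export
equilibriumIndexMap <- function(equilibriumOffsets) {
  eq <- sort(as.numeric(equilibriumOffsets))
  nUp <- sum(eq < 0)
  idx <- c(rev(-seq_len(nUp)), seq_len(length(eq) - nUp))
  stats::setNames(eq, idx)
}
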