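#' Per-gene occupancy features around the TSS
#'
#' The k-means feature matrix: per-gene signal in an even window centred on
#' the TSS (offsets \code{-window/2 .. window/2 - 1}), strand-oriented.
#' Same machinery as \code{\link{alignToAnchor}}.
#'
#' @param track a \code{\linkS4class{BinaryTrack}} or
#'   \code{\linkS4class{RealTrack}}.
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param window even window width (bp, default 1600).
#' @return a \code{\linkS4class{GeneMatrix}} with \code{window} columns.
#' @export
occupancyFeatureMatrix <- function(track, annotation, window = 1600L) {
  if (window %% 2L != 0L) stop("window must be even")
  half <- window %/% 2L
  geneSignalMatrix(track, annotation, "TSS",
                   seq.int(-half, half - 1L))
}

#' Cluster genes by promoter occupancy pattern
#'
#' Euclidean k-means on the rows of the feature matrix, best of
#' \code{restarts} random initialisations; clusters are relabelled in
#' decreasing order of mean occupancy over the +1 region (offsets 0..150)
#' so labels are stable across runs.
#'
#' @param features a \code{\linkS4class{GeneMatrix}}.
#' @param k number of clusters (default 4).
#' @param restarts random restarts (default 10).
#' @param seed RNG seed.
#' @return list with \code{assignment} (named integer vector), \code{k},
#'   \code{inertia}, \code{centers}, \code{seed}.
#' @export
clusterGenes <- function(features, k = 4L, restarts = 10L, seed = 1L) {
  stopifnot(is(features, "GeneMatrix"), k >= 1L)
  x <- features@signal
  if (nrow(x) < k) stop("fewer genes than clusters")
  if (nrow(unique(x)) < k)
    stop("degenerate features: fewer than k distinct rows")
  km <- withSeed(deriveSeed(seed, "kmeans"),
                 stats::kmeans(x, centers = k, nstart = restarts,
                               iter.max = 50L))
  plusCols <- which(features@offsets >= 0L & features@offsets <= 150L)
  occ <- if (length(plusCols)) rowMeans(km$centers[, plusCols, drop = FALSE])
         else rowMeans(km$centers)
  relab <- match(seq_len(k), order(-occ))
  assignment <- stats::setNames(relab[km$cluster], features@geneIds)
  list(assignment = assignment, k = as.integer(k),
       inertia = km$tot.withinss,
       centers = km$centers[order(-occ), , drop = FALSE], seed = seed)
}

#' Group frequency as a function of a gene property
#'
#' Genes are sorted by the property and scanned with a sliding window of
#' \code{windowGenes} consecutive genes (the equal-subset size
#' \code{ceiling(N / nSubsets)} when not given); for each window the
#' percentage of genes in each cluster and the window's mean property are
#' recorded.
#'
#' @param assignment named cluster vector from \code{\link{clusterGenes}}.
#' @param property named numeric property values (names = gene ids).
#' @param windowGenes genes per window; default \code{ceiling(N/nSubsets)}.
#' @param nSubsets number of equal subsets used to derive the window size
#'   (default 23).
#' @return data.frame with \code{window}, \code{mean_property},
#'   \code{group}, \code{percent}.
#' @export
groupFrequencyCurves <- function(assignment, property, windowGenes = NULL,
                                 nSubsets = 23L) {
  ids <- intersect(names(assignment), names(property)[!is.na(property)])
  if (!length(ids)) stop("no genes with both cluster and property")
  prop <- property[ids]
  grp <- assignment[ids]
  N <- length(ids)
  if (is.null(windowGenes)) windowGenes <- as.integer(ceiling(N / nSubsets))
  if (windowGenes > N) stop("fewer genes than the window size")
  ord <- order(prop)
  prop <- prop[ord]; grp <- grp[ord]
  groupsK <- sort(unique(assignment))
  starts <- seq_len(N - windowGenes + 1L)
  csProp <- cumsum(c(0, prop))
  meanProp <- (csProp[starts + windowGenes] - csProp[starts]) / windowGenes
  out <- list()
  for (g in groupsK) {
    ind <- cumsum(c(0, as.integer(grp == g)))
    pct <- 100 * (ind[starts + windowGenes] - ind[starts]) / windowGenes
    out[[as.character(g)]] <- data.frame(window = starts,
                                         mean_property = meanProp,
                                         group = g, percent = pct)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "windowGenes") <- windowGenes
  res
}

#' Pairwise tests of promoter occupancy density between gene groups
#'
#' Welch two-sample t-tests of a per-gene density between every pair of
#' clusters.
#'
#' @param assignment named cluster vector.
#' @param density named numeric per-gene promoter occupancy density.
#' @return data.frame with \code{group1}, \code{group2}, \code{mean1},
#'   \code{mean2}, \code{t}, \code{p}.
#' @export
groupDensityTest <- function(assignment, density) {
  ids <- intersect(names(assignment), names(density)[!is.na(density)])
  grp <- assignment[ids]
  den <- density[ids]
  gs <- sort(unique(grp))
  if (length(gs) < 2L) stop("need at least 2 groups")
  rows <- list()
  for (i in seq_along(gs)[-length(gs)]) for (j in (i + 1L):length(gs)) {
    a <- den[grp == gs[i]]; b <- den[grp == gs[j]]
    if (length(a) < 2L || length(b) < 2L) stop("group with fewer than 2 genes")
    tt <- stats::t.test(a, b)
    rows[[length(rows) + 1L]] <-
      data.frame(group1 = gs[i], group2 = gs[j],
                 mean1 = mean(a), mean2 = mean(b),
                 t = unname(tt$statistic), p = tt$p.value)
  }
  do.call(rbind, rows)
}

#' Local regulatory correlation (LRC) map
#'
#' For every (window width, window centre) pair, the Pearson correlation
#' across genes between the window-mean occupancy and a gene property.
#' Windows are clipped to the feature matrix's offset range.
#'
#' @param features a \code{\linkS4class{GeneMatrix}} of one track class
#'   (stable or dynamic).
#' @param property named numeric property values (names = gene ids).
#' @param widths window widths in bp (default \code{seq(100, 600, 10)}).
#' @param positionStep step of the window start position (bp, default 1).
#' @return data.frame with \code{width}, \code{centre}, \code{r}, \code{n};
#'   zero-variance windows have \code{r = NA}.
#' @export
lrcMap <- function(features, property,
                   widths = seq(100L, 600L, by = 10L), positionStep = 1L) {
  stopifnot(is(features, "GeneMatrix"), positionStep >= 1L)
  ids <- intersect(features@geneIds, names(property)[!is.na(property)])
  if (length(ids) < 3L) stop("need at least 3 genes with property values")
  x <- features@signal[match(ids, features@geneIds), , drop = FALSE]
  y <- property[ids]
  n <- length(ids)
  y0 <- y - mean(y)
  sy <- sqrt(sum(y0^2))
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  offs <- features@offsets
  out <- list()
  for (w in widths) {
    if (w > ncol(x)) next
    starts <- seq.int(1L, ncol(x) - w + 1L, by = positionStep)
    wm <- (cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]) / w
    wc <- sweep(wm, 2L, colMeans(wm))
    sx <- sqrt(colSums(wc^2))
    r <- as.numeric(crossprod(wc, y0)) / (sx * sy)
    r[sx == 0] <- NA_real_
    out[[as.character(w)]] <-
      data.frame(width = w, centre = offs[starts] + (w - 1) / 2, r = r, n = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# strand-oriented dyad offsets of a call set per gene
callOffsetsByGene <- function(calls, annotation, maxOffset = 1200L) {
  cl <- nucCalls(calls)
  g <- genes(annotation)
  res <- vector("list", nrow(g))
  names(res) <- g$gene_id
  byChrom <- split(cl$dyad, cl$chrom)
  for (i in seq_len(nrow(g))) {
    dy <- byChrom[[g$chrom[i]]]
    if (is.null(dy)) { res[[i]] <- numeric(0); next }
    off <- orientOffset(dy, g$tss[i], g$strand[i])
    res[[i]] <- sort(off[abs(off) <= maxOffset])
  }
  res
}

#' Distance between the +1 nucleosome dyad and the TSS
#'
#' The +1 nucleosome of a gene is the call whose dyad has the smallest
#' non-negative strand-oriented offset within \code{searchWindow} of the
#' TSS. The reported distance is TSS - dyad, so a dyad 60 bp downstream
#' gives -60. Genes are binned by distance and the mean of each property
#' per bin is reported with a percentile bootstrap interval.
#'
#' @param calls a \code{\linkS4class{NucleosomeCallSet}} of stable calls
#'   (e.g. from \code{\link{callsFromBinaryTrack}} on the AND consensus).
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param properties optional data.frame with \code{gene_id} and numeric
#'   property columns.
#' @param searchWindow strand-oriented offsets admissible for the +1 dyad
#'   (default 0..120: wide enough for any jittered +1 dyad, but ending
#'   before the first counterphase midpoint (~+140) and the +2 position,
#'   so a gene with no detected +1 is excluded rather than silently
#'   assigned a destabilised or +2 call).
#' @param binWidth distance bin width (bp, default 10).
#' @param nBoot bootstrap resamples per bin (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{distances} (per-gene table), \code{curves}
#'   (per-bin property means + CI) and \code{nExcluded}.
#' @export
plusOneDistanceAnalysis <- function(calls, annotation, properties = NULL,
                                    searchWindow = c(0L, 120L),
                                    binWidth = 10L, nBoot = 200L,
                                    seed = 1L) {
  offs <- callOffsetsByGene(calls, annotation,
                            maxOffset = max(abs(searchWindow)) + 1L)
  plus1 <- vapply(offs, function(o) {
    o <- o[o >= searchWindow[1L] & o <= searchWindow[2L]]
    if (!length(o)) NA_real_ else min(o)
  }, numeric(1))
  ok <- !is.na(plus1)
  dist <- data.frame(gene_id = names(plus1)[ok],
                     plus_one_offset = plus1[ok],
                     distance = -plus1[ok], stringsAsFactors = FALSE)
  curves <- NULL
  if (!is.null(properties) && nrow(dist)) {
    pm <- merge(dist, properties, by = "gene_id")
    bins <- binWidth * floor(pm$distance / binWidth)
    propNames <- setdiff(names(properties), "gene_id")
    rows <- list()
    for (pn in propNames) {
      sp <- split(pm[[pn]], bins)
      for (b in names(sp)) {
        v <- sp[[b]][!is.na(sp[[b]])]
        if (!length(v)) next
        ci <- bootstrapCI(v, nBoot = nBoot,
                          seed = deriveSeed(seed, paste(pn, b)))
        rows[[length(rows) + 1L]] <-
          data.frame(property = pn, bin = as.numeric(b), n = length(v),
                     mean = ci$estimate, low = ci$low, high = ci$high)
      }
    }
    curves <- do.call(rbind, rows)
  }
  list(distances = dist, curves = curves, nExcluded = sum(!ok))
}

#' Contrast TATA-containing and TATA-free promoters
#'
#' Splits genes by TATA label, reports the mean +1 dyad-TSS offset per
#' class with bootstrap standard errors, their difference, and bootstrap
#' summaries of each gene property per class. Optionally computes
#' class-wise composite profiles from a supplied track.
#'
#' @param calls stable \code{\linkS4class{NucleosomeCallSet}} used for +1
#'   assignment.
#' @param annotation a \code{\linkS4class{GenomeAnnotation}} with TATA
#'   labels.
#' @param properties optional property data.frame (\code{gene_id} +
#'   numeric columns).
#' @param track optional track for class-wise composite profiles.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with \code{plusOne} (per-class offset summary),
#'   \code{difference} (TATA-free minus TATA mean offset, with CI),
#'   \code{propertyContrast}, and \code{profiles} when a track is given.
#' @export
tataContrast <- function(calls, annotation, properties = NULL, track = NULL,
                         nBoot = 1000L, seed = 1L) {
  g <- genes(annotation)
  if (!any(g$tata) || !any(!g$tata))
    stop("both TATA classes must be non-empty")
  p1 <- plusOneDistanceAnalysis(calls, annotation, properties = NULL,
                                nBoot = 1L, seed = seed)$distances
  p1$tata <- g$tata[match(p1$gene_id, g$gene_id)]
  summ <- lapply(split(p1$plus_one_offset, p1$tata), function(v) {
    ci <- bootstrapCI(v, nBoot = nBoot, seed = deriveSeed(seed, "p1"))
    data.frame(n = length(v), mean_offset = mean(v),
               low = ci$low, high = ci$high)
  })
  plusOne <- cbind(tata = c(FALSE, TRUE),
                   do.call(rbind, summ[c("FALSE", "TRUE")]))
  dObs <- plusOne$mean_offset[plusOne$tata == FALSE] -
    plusOne$mean_offset[plusOne$tata == TRUE]
  dBoot <- withSeed(deriveSeed(seed, "diff"), {
    a <- p1$plus_one_offset[p1$tata]
    b <- p1$plus_one_offset[!p1$tata]
    if (nBoot > 1L)
      vapply(seq_len(nBoot), function(i)
        mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE)),
        numeric(1))
    else dObs
  })
  diffRes <- list(estimate = dObs,
                  low = unname(stats::quantile(dBoot, 0.025)),
                  high = unname(stats::quantile(dBoot, 0.975)))
  propertyContrast <- NULL
  if (!is.null(properties)) {
    pm <- merge(g[, c("gene_id", "tata")], properties, by = "gene_id")
    rows <- list()
    for (pn in setdiff(names(properties), "gene_id")) {
      for (tt in c(FALSE, TRUE)) {
        v <- pm[[pn]][pm$tata == tt & !is.na(pm[[pn]])]
        ci <- bootstrapCI(v, nBoot = nBoot,
                          seed = deriveSeed(seed, paste(pn, tt)))
        rows[[length(rows) + 1L]] <-
          data.frame(property = pn, tata = tt, n = length(v),
                     mean = ci$estimate, low = ci$low, high = ci$high)
      }
    }
    propertyContrast <- do.call(rbind, rows)
  }
  profiles <- NULL
  if (!is.null(track)) {
    profiles <- lapply(c(`FALSE` = FALSE, `TRUE` = TRUE), function(tt) {
      sub <- GenomeAnnotation(g[g$tata == tt, , drop = FALSE],
                              chromSizes(annotation))
      compositeProfile(alignToAnchor(track, sub, "TSS", 800L))
    })
  }
  list(plusOne = plusOne, difference = diffRes,
       propertyContrast = propertyContrast, profiles = profiles)
}
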