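#' Stable consensus by logical AND
#'
#' Site-wise conjunction of N binary tracks: 1 exactly where every dataset
#' calls the base nucleosomal. This is the stable nucleosome track.
#'
#' @param tracks list of \code{\linkS4class{BinaryTrack}} objects (>= 2,
#'   equal lengths per chromosome).
#' @return a \code{\linkS4class{BinaryTrack}}.
#' @export
logicalAndStack <- function(tracks) {
  k <- stackCounts(tracks)
  n <- length(tracks)
  new("BinaryTrack", values = lapply(k, function(v) as.integer(v == n)))
}

#' Dynamic disagreement by averaged pairwise XOR
#'
#' The arithmetic mean of all C(n,2) pairwise XOR tracks. At a site where
#' k of the n datasets call occupancy, the number of discordant pairs is
#' k(n-k), so the mean equals k(n-k)/C(n,2); this closed form is what is
#' computed. The result is the dynamic nucleosome track.
#'
#' @param tracks list of \code{\linkS4class{BinaryTrack}} objects (>= 2,
#'   equal lengths per chromosome).
#' @return a \code{\linkS4class{RealTrack}} in [0, 1] with attribute
#'   \code{"n_pairs"} = C(n,2).
#' @export
xorMeanStack <- function(tracks) {
  k <- stackCounts(tracks)
  n <- length(tracks)
  nPairs <- choose(n, 2)
  out <- new("RealTrack",
             values = lapply(k, function(v) v * (n - v) / nPairs),
             unit = "xor_mean")
  attr(out, "n_pairs") <- nPairs
  out
}

#' Binomial decomposition of the per-site occupancy frequency
#'
#' Treats the n binary datasets as i.i.d. samples of a per-site occupancy
#' probability. With p(i) the observed frequency of occupancy at site i,
#' the probability of seeing exactly k occupied datasets is
#' P\{X(i)=k\} = C(n,k) p(i)^k (1-p(i))^(n-k); one probability track is
#' produced per k = 0..n. By default k = 0 is labelled NFR,
#' 1 <= k <= n-2 dynamic and k >= n-1 stable.
#'
#' @param tracks list of \code{\linkS4class{BinaryTrack}} objects (>= 2).
#' @param stableMinK smallest k counted as stable (default n-1).
#' @return a \code{\linkS4class{BDIDProfiles}} object.
#' @export
bdidDecompose <- function(tracks, stableMinK = length(tracks) - 1L) {
  k <- stackCounts(tracks)
  n <- length(tracks)
  pvals <- lapply(k, function(v) v / n)
  profiles <- lapply(0:n, function(kk)
    new("RealTrack",
        values = lapply(pvals, function(p) stats::dbinom(kk, n, p)),
        unit = sprintf("P(X=%d)", kk)))
  names(profiles) <- paste0("k", 0:n)
  groups <- ifelse(0:n == 0L, "NFR",
                   ifelse(0:n >= stableMinK, "stable", "dynamic"))
  new("BDIDProfiles", n = as.integer(n),
      p = new("RealTrack", values = pvals, unit = "frequency"),
      profiles = profiles, groups = groups)
}

#' Aggregate BDID probability tracks over a group
#'
#' @param bdid a \code{\linkS4class{BDIDProfiles}}.
#' @param group \code{"NFR"}, \code{"dynamic"} or \code{"stable"}.
#' @return a \code{\linkS4class{RealTrack}}: the summed probability of the
#'   group's k values at each site.
#' @export
bdidGroupTrack <- function(bdid, group = c("stable", "dynamic", "NFR")) {
  group <- match.arg(group)
  stopifnot(is(bdid, "BDIDProfiles"))
  sel <- which(bdid@groups == group)
  if (!length(sel)) stop("no k values in group ", group)
  chroms <- names(trackValues(bdid@p))
  vals <- lapply(stats::setNames(nm = chroms), function(ch) {
    acc <- trackValues(bdid@profiles[[sel[1L]]], ch)
    for (j in sel[-1L]) acc <- acc + trackValues(bdid@profiles[[j]], ch)
    acc
  })
  new("RealTrack", values = vals, unit = paste0("P(", group, ")"))
}

# Strand-oriented genomic positions of a region for every gene; returns a
# list of index vectors (1-based into the chromosome vector), NULL when the
# region leaves the chromosome.
regionIndices <- function(annotation, region, chromLens) {
  g <- genes(annotation)
  lapply(seq_len(nrow(g)), function(i) {
    tss <- g$tss[i]; tts <- g$tts[i]; strand <- g$strand[i]
    span <- switch(region,
      promoter = c(-400L, -1L),
      TSS = c(-200L, 199L),
      `5CDS` = c(0L, 399L),
      midCDS = {
        m <- orientOffset((tss + tts) %/% 2L, tss, strand)
        c(m - 200L, m + 199L)
      },
      `3CDS` = {
        gl <- abs(tts - tss)
        c(gl - 400L, gl - 1L)
      },
      TTS = {
        gl <- abs(tts - tss)
        c(gl - 200L, gl + 199L)
      },
      stop("unknown region: ", region))
    off <- span[1L]:span[2L]
    pos <- orientPosition(off, tss, strand)
    if (min(pos) < 0L || max(pos) >= chromLens[[g$chrom[i]]]) return(NULL)
    pos + 1L
  })
}

#' Pairwise Pearson correlations between datasets in genomic regions
#'
#' For \code{region = "genome"} tracks are compared over the whole genome;
#' for gene-anchored regions the per-gene 400-bp segments (strand-oriented)
#' are concatenated before correlating. Pairs with zero variance are
#' reported as NA and excluded from the mean.
#'
#' @param tracks named list of \code{\linkS4class{BinaryTrack}} or
#'   \code{\linkS4class{RealTrack}} objects.
#' @param annotation a \code{\linkS4class{GenomeAnnotation}} (required for
#'   non-genome regions).
#' @param regions subset of \code{c("genome", "promoter", "TSS", "5CDS",
#'   "midCDS", "3CDS", "TTS")}.
#' @return list of reports, one per region, each with elements
#'   \code{region}, \code{r} (correlation matrix) and \code{mean_r} (mean
#'   off-diagonal, NA-excluded).
#' @export
datasetCorrelations <- function(tracks, annotation = NULL,
                                regions = "genome") {
  checkTrackStack(tracks)
  known <- c("genome", "promoter", "TSS", "5CDS", "midCDS", "3CDS", "TTS")
  bad <- setdiff(regions, known)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  if (any(regions != "genome") && is.null(annotation))
    stop("gene-anchored regions need an annotation")
  nm <- names(tracks)
  if (is.null(nm)) nm <- paste0("track", seq_along(tracks))
  chromLens <- chromSizes(tracks[[1L]])
  lapply(stats::setNames(nm = regions), function(region) {
    segs <- if (region == "genome") NULL
            else regionIndices(annotation, region, chromLens)
    mat <- vapply(tracks, function(tr) {
      if (region == "genome") {
        unlist(lapply(names(trackValues(tr)), function(ch)
          as.numeric(trackValues(tr, ch))), use.names = FALSE)
      } else {
        g <- genes(annotation)
        unlist(lapply(seq_along(segs), function(i) {
          if (is.null(segs[[i]])) return(numeric(0))
          as.numeric(trackValues(tr, g$chrom[i])[segs[[i]]])
        }), use.names = FALSE)
      }
    }, numeric(if (region == "genome") sum(chromLens)
               else sum(lengths(segs) > 0) * 400L))
    r <- suppressWarnings(stats::cor(mat))
    sds <- apply(mat, 2L, stats::sd)
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
    diag(r)[sds > 0] <- 1
    dimnames(r) <- list(nm, nm)
    off <- r[upper.tri(r)]
    list(region = region, r = r,
         mean_r = if (all(is.na(off))) NA_real_ else mean(off, na.rm = TRUE))
  })
}

#' Split two occupancy tracks into common and independent components
#'
#' Standardises both tracks and eigendecomposes their 2x2 covariance. The
#' projection on the same-sign (sum) axis is the common component, the
#' projection on the mixed-sign (difference) axis the independent one; for
#' uncorrelated inputs the axes fall back to eigenvalue order.
#'
#' @param a,b \code{\linkS4class{RealTrack}} objects of equal layout.
#' @return list with \code{common} and \code{independent}
#'   \code{\linkS4class{RealTrack}}s plus the \code{rotation} matrix and
#'   \code{eigenvalues}.
#' @export
decomposeOccupancyPair <- function(a, b) {
  chroms <- checkTrackStack(list(a, b))
  za <- unlist(lapply(chroms, function(ch) trackValues(a, ch)),
               use.names = FALSE)
  zb <- unlist(lapply(chroms, function(ch) trackValues(b, ch)),
               use.names = FALSE)
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop("zero-variance input track")
  za <- as.numeric(scale(za)); zb <- as.numeric(scale(zb))
  C <- stats::cov(cbind(za, zb))
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors
  sameSign <- apply(v, 2L, function(x) prod(sign(x)) > 0)
  ci <- if (xor(sameSign[1L], sameSign[2L])) which(sameSign) else 1L
  ii <- setdiff(1:2, ci)
  common <- za * v[1L, ci] + zb * v[2L, ci]
  indep <- za * v[1L, ii] + zb * v[2L, ii]
  lens <- chromSizes(a)
  splitBack <- function(x) {
    out <- list(); at <- 0L
    for (ch in chroms) {
      out[[ch]] <- x[(at + 1L):(at + lens[[ch]])]
      at <- at + lens[[ch]]
    }
    out
  }
  list(common = new("RealTrack", values = splitBack(common), unit = "common"),
       independent = new("RealTrack", values = splitBack(indep),
                         unit = "independent"),
       rotation = v[, c(ci, ii)], eigenvalues = eg$values[c(ci, ii)])
}

#' Threshold a probability track into a binary track
#'
#' @param track a \code{\linkS4class{RealTrack}} (e.g. a BDID group
#'   probability track).
#' @param threshold values >= threshold become 1 (default 0.5).
#' @return a \code{\linkS4class{BinaryTrack}}.
#' @export
thresholdTrack <- function(track, threshold = 0.5) {
  stopifnot(is(track, "RealTrack"))
  new("BinaryTrack",
      values = lapply(trackValues(track), function(v)
        as.integer(v >= threshold)))
}
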