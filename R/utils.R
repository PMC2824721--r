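# internal helpers shared across modules

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  code
}

# Deterministic derived seed below 2^31 for a (seed, tag) pair.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (seq_along(utf8ToInt(as.character(tag))) %% 97L + 1L))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

# Strand-oriented offset of genomic positions relative to an anchor.
orientOffset <- function(pos, anchor, strand) {
  (pos - anchor) * ifelse(strand == "+", 1L, -1L)
}

# Genomic position of a strand-oriented offset.
orientPosition <- function(offset, anchor, strand) {
  anchor + offset * ifelse(strand == "+", 1L, -1L)
}

# Validate a list of tracks: >= 2, same chromosomes, same lengths.
checkTrackStack <- function(tracks) {
  if (length(tracks) < 2L)
    stop("need at least 2 tracks", call. = FALSE)
  sz <- lapply(tracks, chromSizes)
  ref <- sz[[1L]]
  for (s in sz[-1L]) {
    if (!identical(sort(names(s)), sort(names(ref))) ||
        !identical(unname(s[names(ref)]), unname(ref)))
      stop("tracks have mismatched chromosomes or lengths", call. = FALSE)
  }
  names(ref)
}

# Sum per-chromosome integer vectors across binary tracks.
stackCounts <- function(tracks) {
  chroms <- checkTrackStack(tracks)
  out <- list()
  for (ch in chroms) {
    acc <- trackValues(tracks[[1L]], ch)
    for (tr in tracks[-1L]) acc <- acc + trackValues(tr, ch)
    out[[ch]] <- acc
  }
  out
}

#' Construct a BinaryTrack
#' @param values named list of integer 0/1 vectors (or a single vector with
#'   \code{chrom} given).
#' @param chrom chromosome name when \code{values} is a single vector.
#' @return a \code{BinaryTrack}.
#' @export
BinaryTrack <- function(values, chrom = "chrI") {
  if (!is.list(values)) {
    values <- stats::setNames(list(as.integer(values)), chrom)
  } else {
    values <- lapply(values, as.integer)
  }
  new("BinaryTrack", values = values)
}

#' Construct a RealTrack
#' @param values named list of numeric vectors (or a single vector with
#'   \code{chrom} given).
#' @param chrom chromosome name when \code{values} is a single vector.
#' @param unit free-text unit label.
#' @return a \code{RealTrack}.
#' @export
RealTrack <- function(values, chrom = "chrI", unit = "") {
  if (!is.list(values))
    values <- stats::setNames(list(as.numeric(values)), chrom)
  new("RealTrack", values = lapply(values, as.numeric), unit = unit)
}
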