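#' Construct a GenomeAnnotation
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{tts}, \code{tata}, \code{class}
#'   (missing \code{tata}/\code{class} are filled with FALSE/"unknown").
#' @param chromSizes named integer vector of chromosome lengths.
#' @return a validated \code{\linkS4class{GenomeAnnotation}}.
#' @export
GenomeAnnotation <- function(genes, chromSizes) {
  if (is.null(genes$tata)) genes$tata <- FALSE
  if (is.null(genes$class)) genes$class <- "unknown"
  genes$tata <- as.logical(genes$tata)
  genes$tss <- as.integer(genes$tss)
  genes$tts <- as.integer(genes$tts)
  sz <- as.integer(chromSizes)
  names(sz) <- names(chromSizes)
  new("GenomeAnnotation", genes = as.data.frame(genes), chromSizes = sz)
}

#' Read a gene annotation TSV
#'
#' Expects a tab-separated table with header columns \code{gene_id},
#' \code{chrom}, \code{strand}, \code{tss}, \code{tts}, \code{tata},
#' \code{class}, preceded by one \code{#chrom_size<TAB>name<TAB>length}
#' comment line per chromosome (as written by
#' \code{\link{writeAnnotation}}). Chromosome sizes can instead be passed
#' explicitly. Gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param chromSizes optional named integer vector overriding the header.
#' @return a validated \code{\linkS4class{GenomeAnnotation}}.
#' @export
readAnnotation <- function(path, chromSizes = NULL) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  hdr <- grep("^#chrom_size\t", lines, value = TRUE)
  if (is.null(chromSizes)) {
    if (!length(hdr))
      stop("no #chrom_size header lines and no chromSizes given: ", path)
    parts <- strsplit(sub("^#chrom_size\t", "", hdr), "\t", fixed = TRUE)
    chromSizes <- stats::setNames(
      vapply(parts, function(p) as.integer(p[2L]), integer(1)),
      vapply(parts, `[`, character(1), 1L))
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("annotation file has no table: ", path)
  g <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tts")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("annotation is missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id at line ",
         which(duplicated(g$gene_id))[1L] + 1L, ": ",
         g$gene_id[duplicated(g$gene_id)][1L])
  if (!is.null(g$tata) && !is.logical(g$tata)) g$tata <- g$tata %in% c(1, "1", "TRUE", "true")
  GenomeAnnotation(g, chromSizes)
}

#' Write a gene annotation TSV
#'
#' @param annotation a \code{\linkS4class{GenomeAnnotation}}.
#' @param path output path (".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  sz <- chromSizes(annotation)
  writeLines(sprintf("#chrom_size\t%s\t%d", names(sz), sz), con)
  g <- genes(annotation)
  g$tata <- as.integer(g$tata)
  utils::write.table(g, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a NucleosomeCallSet
#'
#' @param calls data.frame with \code{chrom}, \code{start}, \code{end} (bp,
#'   0-based half-open); \code{dyad} defaults to the interval midpoint.
#' @param name dataset label.
#' @param condition \code{"normal"} or \code{"heat_shock"}.
#' @return a validated \code{\linkS4class{NucleosomeCallSet}}.
#' @export
NucleosomeCallSet <- function(calls, name = "calls", condition = "normal") {
  calls <- as.data.frame(calls)
  calls$start <- as.integer(calls$start)
  calls$end <- as.integer(calls$end)
  if (is.null(calls$dyad))
    calls$dyad <- (calls$start + calls$end) %/% 2L
  calls$dyad <- as.integer(calls$dyad)
  calls <- calls[order(calls$chrom, calls$start),
                 c("chrom", "start", "end", "dyad"), drop = FALSE]
  rownames(calls) <- NULL
  new("NucleosomeCallSet", name = name, condition = condition, calls = calls)
}

#' Read nucleosome calls from a BED file
#'
#' BED3+ input; the dyad is taken as \code{floor((start + end) / 2)} and
#' calls are sorted by (chrom, start). Overlapping calls are retained,
#' unsorted input is sorted, any strand column is ignored.
#'
#' @param path BED file (gzip transparent).
#' @param name dataset label (default: file base name).
#' @param condition condition label.
#' @return a \code{\linkS4class{NucleosomeCallSet}}.
#' @export
readCalls <- function(path, name = NULL,
                      condition = c("normal", "heat_shock")) {
  condition <- match.arg(condition)
  if (is.null(name))
    name <- sub("\\.(bed)(\\.gz)?$", "", basename(path))
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  NucleosomeCallSet(df, name = name, condition = condition)
}

#' Write nucleosome calls as 6-column BED
#'
#' @param callset a \code{\linkS4class{NucleosomeCallSet}}.
#' @param path output path (".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
writeCalls <- function(callset, path) {
  stopifnot(is(callset, "NucleosomeCallSet"))
  cl <- nucCalls(callset)
  gr <- GenomicRanges::GRanges(cl$chrom,
                               IRanges::IRanges(cl$start + 1L, cl$end))
  if (nrow(cl)) {
    S4Vectors::mcols(gr)$name <- sprintf("%s_%d", callset@name,
                                         seq_len(nrow(cl)))
    S4Vectors::mcols(gr)$score <- 0L
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Binarize a call set into a 0/1 occupancy track
#'
#' Every base within \code{dyad +/- floor(footprint/2)} (or within the
#' reported call interval when \code{useIntervals = TRUE}) is set to 1,
#' overlaps coalescing; everything else is 0. Windows are truncated, not
#' rejected, at chromosome edges.
#'
#' @param callset a \code{\linkS4class{NucleosomeCallSet}}.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param footprint footprint width (bp) for dyad mode (default 147).
#' @param useIntervals use the reported intervals instead of a fixed
#'   footprint around the dyad.
#' @return a \code{\linkS4class{BinaryTrack}}.
#' @export
binarizeCalls <- function(callset, chromSizes, footprint = 147L,
                          useIntervals = FALSE) {
  stopifnot(is(callset, "NucleosomeCallSet"))
  if (!useIntervals && footprint < 1L) stop("footprint must be >= 1")
  half <- as.integer(footprint) %/% 2L
  cl <- nucCalls(callset)
  vals <- lapply(stats::setNames(nm = names(chromSizes)), function(ch) {
    L <- as.integer(chromSizes[[ch]])
    cc <- cl[cl$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) return(integer(L))
    if (useIntervals) {
      s <- pmax(cc$start, 0L); e <- pmin(cc$end, L)
    } else {
      s <- pmax(cc$dyad - half, 0L)
      e <- pmin(cc$dyad - half + as.integer(footprint), L)
    }
    ok <- s < e
    cov <- IRanges::coverage(IRanges::IRanges(start = s[ok] + 1L,
                                              end = e[ok]), width = L)
    as.integer(as.integer(cov) > 0L)
  })
  new("BinaryTrack", values = vals)
}

#' Extract calls from runs of ones in a binary track
#'
#' Maximal runs of 1s at least \code{minRun} bp long become calls with the
#' run midpoint as dyad; used to turn the stable (logical-AND) consensus
#' track back into a positional call set.
#'
#' @param track a \code{\linkS4class{BinaryTrack}}.
#' @param minRun minimal run length to keep (default 74 bp, half a
#'   canonical footprint).
#' @param name label for the resulting call set.
#' @return a \code{\linkS4class{NucleosomeCallSet}}.
#' @export
callsFromBinaryTrack <- function(track, minRun = 74L, name = "consensus") {
  stopifnot(is(track, "BinaryTrack"))
  rows <- list()
  for (ch in names(trackValues(track))) {
    v <- trackValues(track, ch)
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths            # 0-based starts
    keep <- r$values == 1L & r$lengths >= minRun
    if (any(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = s[keep], end = e[keep],
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(NucleosomeCallSet(
      data.frame(chrom = character(), start = integer(), end = integer()),
      name = name))
  NucleosomeCallSet(do.call(rbind, rows), name = name)
}

#' Write a real-valued track as bedGraph
#'
#' Values are run-length encoded, so step-constant tracks round-trip
#' exactly.
#'
#' @param track a \code{\linkS4class{RealTrack}} or
#'   \code{\linkS4class{BinaryTrack}}.
#' @param path output path (".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
writeTrack <- function(track, path) {
  grl <- list()
  for (ch in names(trackValues(track))) {
    v <- as.numeric(trackValues(track, ch))
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    grl[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(s + 1L, e), score = r$values)
  }
  gr <- do.call(c, unname(grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a RealTrack
#'
#' Overlapping intervals and intervals past the chromosome end are
#' rejected; uncovered positions are 0.
#'
#' @param path bedGraph file (gzip transparent).
#' @param chromSizes named integer vector of chromosome lengths.
#' @param unit unit label for the track.
#' @return a \code{\linkS4class{RealTrack}}.
#' @export
readTrack <- function(path, chromSizes, unit = "") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$chrom), names(chromSizes))
  if (length(bad))
    stop("bedGraph chromosome(s) not in chromSizes: ",
         paste(bad, collapse = ", "))
  vals <- lapply(stats::setNames(nm = names(chromSizes)), function(ch) {
    L <- as.integer(chromSizes[[ch]])
    cc <- df[df$chrom == ch, , drop = FALSE]
    v <- numeric(L)
    if (!nrow(cc)) return(v)
    if (any(cc$end > L) || any(cc$start < 0L))
      stop("bedGraph interval outside chromosome '", ch, "'")
    cc <- cc[order(cc$start), , drop = FALSE]
    if (any(cc$start[-1L] < cc$end[-nrow(cc)]))
      stop("overlapping bedGraph intervals on chromosome '", ch, "'")
    for (i in seq_len(nrow(cc)))
      v[(cc$start[i] + 1L):cc$end[i]] <- cc$score[i]
    v
  })
  new("RealTrack", values = vals, unit = unit)
}
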