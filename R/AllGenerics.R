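#' Per-chromosome values of a track
#'
#' @param x a \code{BinaryTrack} or \code{RealTrack}.
#' @param chrom optional chromosome name; if given, the vector for that
#'   chromosome is returned instead of the full list.
#' @return named list of vectors, or a single vector when \code{chrom} is
#'   given.
#' @export
setGeneric("trackValues", function(x, chrom = NULL) standardGeneric("trackValues"))

#' Chromosome sizes of an object
#' @param x object carrying chromosome lengths.
#' @return named integer vector of lengths (bp).
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' Gene table of an annotation or layout
#' @param x a \code{GenomeAnnotation} or \code{TrueLayout}.
#' @return data.frame of genes.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Call table of a call set
#' @param x a \code{NucleosomeCallSet}.
#' @return data.frame of calls.
#' @export
setGeneric("nucCalls", function(x) standardGeneric("nucCalls"))

#' Nucleosome table of a true layout
#' @param x a \code{TrueLayout}.
#' @return data.frame of nucleosomes.
#' @export
setGeneric("layoutNucleosomes", function(x) standardGeneric("layoutNucleosomes"))

#' Peak offsets of a PeakSet
#' @param x a \code{PeakSet}.
#' @return numeric vector of peak offsets (bp).
#' @export
setGeneric("peakOffsets", function(x) standardGeneric("peakOffsets"))

setMethod("trackValues", "BinaryTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) x@values else x@values[[chrom]]
})
setMethod("trackValues", "RealTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) x@values else x@values[[chrom]]
})
setMethod("chromSizes", "GenomeAnnotation", function(x) x@chromSizes)
setMethod("chromSizes", "TrueLayout", function(x) x@params$chrom_sizes)
setMethod("chromSizes", "BinaryTrack",
          function(x) vapply(x@values, length, integer(1)))
setMethod("chromSizes", "RealTrack",
          function(x) vapply(x@values, length, integer(1)))
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
setMethod("genes", "TrueLayout", function(x) x@genes)
setMethod("nucCalls", "NucleosomeCallSet", function(x) x@calls)
setMethod("layoutNucleosomes", "TrueLayout", function(x) x@nucleosomes)
setMethod("peakOffsets", "PeakSet", function(x) x@offsets)

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s)\n",
              nrow(object@genes), length(object@chromSizes)))
  cat(sprintf("  TATA-containing: %d; strands +/-: %d/%d\n",
              sum(object@genes$tata),
              sum(object@genes$strand == "+"),
              sum(object@genes$strand == "-")))
})

setMethod("show", "NucleosomeCallSet", function(object) {
  cat(sprintf("NucleosomeCallSet '%s' (%s): %d calls\n",
              object@name, object@condition, nrow(object@calls)))
})

setMethod("show", "BinaryTrack", function(object) {
  sz <- chromSizes(object)
  ones <- sum(vapply(object@values, function(v) sum(v), numeric(1)))
  cat(sprintf("BinaryTrack: %d chromosome(s), %d bp, %.1f%% packaged\n",
              length(sz), sum(sz), 100 * ones / max(1, sum(sz))))
})

setMethod("show", "RealTrack", function(object) {
  sz <- chromSizes(object)
  cat(sprintf("RealTrack%s: %d chromosome(s), %d bp\n",
              if (nzchar(object@unit)) sprintf(" [%s]", object@unit) else "",
              length(sz), sum(sz)))
})

setMethod("show", "BDIDProfiles", function(object) {
  cat(sprintf("BDIDProfiles: n = %d datasets, %d probability tracks\n",
              object@n, length(object@profiles)))
  cat("  groups:", paste(sprintf("k%d=%s", 0:object@n, object@groups),
                         collapse = ", "), "\n")
})

setMethod("show", "TrueLayout", function(object) {
  nuc <- object@nucleosomes
  cat(sprintf("TrueLayout (%s): %d genes, %d nucleosomes (%d stable, %d dynamic)\n",
              object@condition, nrow(object@genes), nrow(nuc),
              sum(nuc$class == "stable"), sum(nuc$class == "dynamic")))
})

setMethod("show", "GeneMatrix", function(object) {
  cat(sprintf("GeneMatrix: %d genes x %d offsets around %s (%d dropped)\n",
              nrow(object@signal), ncol(object@signal), object@anchor,
              object@dropped))
})

setMethod("show", "CompositeProfile", function(object) {
  cat(sprintf("CompositeProfile around %s: offsets %d..%d bp, %d genes\n",
              object@anchor, min(object@offsets), max(object@offsets),
              object@nGenes))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peaks at [%s] bp\n", length(object@offsets),
              paste(round(object@offsets), collapse = ", ")))
})
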