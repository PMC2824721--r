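#' @import methods
NULL

#' Genome annotation of transcripts
#'
#' Holds the gene table (TSS/TTS anchors, strand, TATA label, promoter class)
#' and the chromosome sizes against which all coordinates are validated.
#' Coordinates are 0-based throughout the package; BED files are read and
#' written in their native 0-based half-open convention.
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{tss}, \code{tts},
#'   \code{tata} (logical), \code{class}
#'   (\code{activated}/\code{repressed}/\code{basal}/\code{unknown}).
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
         representation(genes = "data.frame", chromSizes = "integer"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "strand", "tss", "tts", "tata", "class")
  if (!all(need %in% names(g)))
    return(paste("missing gene columns:",
                 paste(setdiff(need, names(g)), collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    return("duplicate gene_id values")
  if (!all(g$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  if (is.null(names(object@chromSizes)) || any(names(object@chromSizes) == ""))
    return("chromSizes must be named")
  if (!all(g$chrom %in% names(object@chromSizes)))
    return("gene chrom not in chromSizes")
  sz <- object@chromSizes[g$chrom]
  if (any(g$tss < 0L | g$tss >= sz))
    return(sprintf("tss out of range for gene '%s'",
                   g$gene_id[which(g$tss < 0L | g$tss >= sz)[1L]]))
  if (any(g$tts < 0L | g$tts >= sz))
    return(sprintf("tts out of range for gene '%s'",
                   g$gene_id[which(g$tts < 0L | g$tts >= sz)[1L]]))
  TRUE
})

#' Nucleosome position call set
#'
#' One platform's nucleosome calls: genomic intervals with a dyad (the
#' footprint midpoint) per call. Intervals are 0-based half-open.
#'
#' @slot name label of the platform or dataset.
#' @slot condition \code{"normal"} or \code{"heat_shock"}.
#' @slot calls data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{dyad}, sorted by (chrom, start).
#' @exportClass NucleosomeCallSet
setClass("NucleosomeCallSet",
         representation(name = "character", condition = "character",
                        calls = "data.frame"))

setValidity("NucleosomeCallSet", function(object) {
  cl <- object@calls
  need <- c("chrom", "start", "end", "dyad")
  if (!all(need %in% names(cl)))
    return(paste("missing call columns:",
                 paste(setdiff(need, names(cl)), collapse = ", ")))
  if (nrow(cl)) {
    if (any(cl$start >= cl$end)) return("call with start >= end")
    if (any(cl$dyad < cl$start | cl$dyad >= cl$end))
      return("dyad outside its call interval")
  }
  if (!object@condition %in% c("normal", "heat_shock"))
    return("condition must be 'normal' or 'heat_shock'")
  TRUE
})

#' Binary occupancy track
#'
#' Per-chromosome 0/1 vectors where 1 marks a nucleosome-packaged base and 0
#' linker DNA: the restructured representation on which all logical
#' integration operates.
#'
#' @slot values named list of integer vectors, one per chromosome.
#' @exportClass BinaryTrack
setClass("BinaryTrack", representation(values = "list"))

setValidity("BinaryTrack", function(object) {
  if (is.null(names(object@values)) || any(names(object@values) == ""))
    return("values must be a named list (one element per chromosome)")
  for (v in object@values) {
    if (!is.integer(v)) return("track vectors must be integer")
    if (length(v) && (min(v) < 0L || max(v) > 1L))
      return("binary track values must be 0 or 1")
  }
  TRUE
})

#' Real-valued genomic track
#'
#' Per-chromosome numeric vectors holding occupancy ratios, XOR-mean
#' disagreement, or binomial probability profiles.
#'
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot unit free-text label of what the values are.
#' @exportClass RealTrack
setClass("RealTrack",
         representation(values = "list", unit = "character"),
         prototype(unit = ""))

setValidity("RealTrack", function(object) {
  if (is.null(names(object@values)) || any(names(object@values) == ""))
    return("values must be a named list (one element per chromosome)")
  for (v in object@values) {
    if (!is.numeric(v)) return("track vectors must be numeric")
    if (length(v) && any(!is.finite(v))) return("track values must be finite")
  }
  TRUE
})

#' Binomial decomposition of n binary tracks
#'
#' Per-site occupancy frequency p(i) across the n datasets together with the
#' n+1 probability tracks P\{X(i)=k\} = C(n,k) p(i)^k (1-p(i))^(n-k),
#' partitioned into NFR (k=0), dynamic (1 <= k <= n-2) and stable
#' (k >= n-1) groups.
#'
#' @slot n number of input datasets.
#' @slot p RealTrack of per-site occupancy frequencies.
#' @slot profiles list of n+1 RealTracks named \code{"k0"} .. \code{"kn"}.
#' @slot groups character vector of length n+1 labelling each k as
#'   \code{"NFR"}, \code{"dynamic"} or \code{"stable"}.
#' @exportClass BDIDProfiles
setClass("BDIDProfiles",
         representation(n = "integer", p = "RealTrack",
                        profiles = "list", groups = "character"))

setValidity("BDIDProfiles", function(object) {
  if (length(object@profiles) != object@n + 1L)
    return("need n+1 probability profiles")
  if (length(object@groups) != object@n + 1L)
    return("need n+1 group labels")
  if (!all(object@groups %in% c("NFR", "dynamic", "stable")))
    return("groups must be NFR/dynamic/stable")
  TRUE
})

#' Ground-truth nucleosome layout
#'
#' The synthetic generator's truth: one row per nucleosome with its class
#' (stable or dynamic), ordinal index relative to the TSS, strand-oriented
#' mean offset and genomic dyad, plus per-gene archetype assignments.
#'
#' @slot condition \code{"normal"} or \code{"heat_shock"}.
#' @slot nucleosomes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{class}, \code{index} (NA for dynamic),
#'   \code{offset}, \code{dyad}, \code{presence_prob}.
#' @slot genes data.frame with columns \code{gene_id}, \code{archetype},
#'   \code{class} (promoter class), \code{tata}.
#' @slot params list of the generator parameters used (includes
#'   \code{chrom_sizes}).
#' @exportClass TrueLayout
setClass("TrueLayout",
         representation(condition = "character", nucleosomes = "data.frame",
                        genes = "data.frame", params = "list"))

setValidity("TrueLayout", function(object) {
  nuc <- object@nucleosomes
  need <- c("gene_id", "chrom", "strand", "class", "index", "offset",
            "dyad", "presence_prob")
  if (!all(need %in% names(nuc)))
    return(paste("missing nucleosome columns:",
                 paste(setdiff(need, names(nuc)), collapse = ", ")))
  if (nrow(nuc) && !all(nuc$class %in% c("stable", "dynamic")))
    return("nucleosome class must be stable or dynamic")
  TRUE
})

#' Genes-by-offsets signal matrix
#'
#' Track signal extracted around an anchor (TSS or TTS) for every usable
#' gene, strand-oriented so that negative offsets are upstream.
#'
#' @slot signal numeric matrix, genes in rows, offsets in columns.
#' @slot offsets integer offsets (bp) relative to the anchor.
#' @slot anchor \code{"TSS"} or \code{"TTS"}.
#' @slot geneIds row gene identifiers.
#' @slot dropped number of genes dropped at chromosome boundaries.
#' @exportClass GeneMatrix
setClass("GeneMatrix",
         representation(signal = "matrix", offsets = "integer",
                        anchor = "character", geneIds = "character",
                        dropped = "integer"))

setValidity("GeneMatrix", function(object) {
  if (ncol(object@signal) != length(object@offsets))
    return("offsets length must match column count")
  if (nrow(object@signal) != length(object@geneIds))
    return("geneIds length must match row count")
  TRUE
})

#' Composite (gene-averaged) profile
#'
#' Column means of a GeneMatrix: the mean signal as a function of offset
#' from the anchor.
#'
#' @slot offsets integer offsets (bp).
#' @slot signal mean signal per offset.
#' @slot nGenes number of genes averaged.
#' @slot anchor \code{"TSS"} or \code{"TTS"}.
#' @exportClass CompositeProfile
setClass("CompositeProfile",
         representation(offsets = "integer", signal = "numeric",
                        nGenes = "integer", anchor = "character"))

#' Detected profile peaks
#'
#' Local maxima of a smoothed composite profile; for the stable consensus
#' these are the stable equilibrium points.
#'
#' @slot offsets peak offsets (bp), strictly increasing.
#' @slot heights smoothed profile height at each peak.
#' @slot params smoothing/detection parameters used.
#' @exportClass PeakSet
setClass("PeakSet",
         representation(offsets = "numeric", heights = "numeric",
                        params = "list"))

setValidity("PeakSet", function(object) {
  if (length(object@offsets) != length(object@heights))
    return("offsets and heights must have equal length")
  if (length(object@offsets) > 1L && any(diff(object@offsets) <= 0))
    return("peak offsets must be strictly increasing")
  TRUE
})
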