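#' Accessors for panel, read and probe containers
#'
#' @param x a \linkS4class{PanelDesign}, \linkS4class{AlignedReads} or
#'   \linkS4class{ProbeTrack} object.
#' @return \code{amplicons}, \code{targets} and \code{reportableRange}
#'   return \code{GRanges}; \code{refSequence} a \code{DNAStringSet};
#'   \code{readRecords} and \code{probes} a \code{data.frame};
#'   \code{noiseSd} and \code{isTrimmed} scalars.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))
#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname accessors
#' @export
setGeneric("reportableRange", function(x) standardGeneric("reportableRange"))
#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname accessors
#' @export
setGeneric("readRecords", function(x) standardGeneric("readRecords"))
#' @rdname accessors
#' @export
setGeneric("isTrimmed", function(x) standardGeneric("isTrimmed"))
#' @rdname accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))
#' @rdname accessors
#' @export
setGeneric("noiseSd", function(x) standardGeneric("noiseSd"))

#' @rdname accessors
#' @export
setMethod("amplicons", "PanelDesign", function(x) x@amplicons)
#' @rdname accessors
#' @export
setMethod("targets", "PanelDesign", function(x) x@targets)
#' @rdname accessors
#' @export
setMethod("reportableRange", "PanelDesign", function(x) x@reportable)
#' @rdname accessors
#' @export
setMethod("refSequence", "PanelDesign", function(x) x@reference)
#' @rdname accessors
#' @export
setMethod("readRecords", "AlignedReads", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("isTrimmed", "AlignedReads", function(x) x@trimmed)
#' @rdname accessors
#' @export
setMethod("probes", "ProbeTrack", function(x) x@probes)
#' @rdname accessors
#' @export
setMethod("noiseSd", "ProbeTrack", function(x) x@noiseSd)

setMethod("show", "PanelDesign", function(object) {
  amp <- object@amplicons
  cat("PanelDesign with", length(amp), "amplicons over",
      length(object@reference), "contig(s)\n")
  if (length(amp))
    cat("  amplicon length:", min(width(amp)), "-", max(width(amp)), "bp\n")
  tgt <- object@targets
  cat("  targets:", length(tgt), "exons (",
      sum(mcols(tgt)$coding), "coding ) in",
      length(unique(mcols(tgt)$gene)), "gene(s)\n")
  cat("  reportable range:", sum(width(object@reportable)), "bp in",
      length(object@reportable), "interval(s)\n")
})

setMethod("show", "AlignedReads", function(object) {
  df <- object@reads
  cat("AlignedReads:", nrow(df), "reads;",
      if (object@trimmed) "primer-trimmed" else "untrimmed", "\n")
  if (nrow(df)) {
    tab <- table(df$status)
    cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  }
})

setMethod("show", "ProbeTrack", function(object) {
  df <- object@probes
  cat("ProbeTrack:", nrow(df), "probes on",
      length(unique(df$contig)), "contig(s)\n")
  if (nrow(df))
    cat("  log2 range:", sprintf("%.3f .. %.3f", min(df$log2),
        max(df$log2)),
        " noise sd:", if (is.na(object@noiseSd)) "unestimated" else
          sprintf("%.4f", object@noiseSd),
        " shift applied:", sprintf("%.4f", object@shift), "\n")
})
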