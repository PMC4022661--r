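#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce granges
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq DNAString
#' @importFrom BiocGenerics sort
#' @useDynLib ampliDx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Tiled amplicon panel design
#'
#' Container for a targeted panel: the tiled amplicons (outer spans with
#' forward/reverse primer footprints, primer sequences as synthesized and
#' adapter tails), the target exons, the reportable range (coding exons plus
#' intronic flank) and the reference sequence.
#'
#' @slot amplicons \code{GRanges} of amplicon outer spans (both primers
#'   included) with metadata columns \code{id}, \code{fwd_len},
#'   \code{rev_len}, \code{fwd_seq}, \code{rev_seq} (reverse primer as
#'   synthesized, i.e. reverse complement of its reference footprint),
#'   \code{fwd_tail}, \code{rev_tail}.
#' @slot targets \code{GRanges} of target exons with metadata columns
#'   \code{gene}, \code{exon} and \code{coding}.
#' @slot reportable \code{GRanges}, merged coding exons extended by the
#'   reporting flank.
#' @slot reference \code{DNAStringSet} with one entry per contig.
#'
#' @seealso [panelDesign()], [validatePanelDesign()], [insertCoverage()]
#' @export
setClass("PanelDesign",
  representation(
    amplicons = "GRanges",
    targets = "GRanges",
    reportable = "GRanges",
    reference = "DNAStringSet"
  )
)

setValidity("PanelDesign", function(object) {
  amp <- object@amplicons
  msg <- character()
  need <- c("id", "fwd_len", "rev_len", "fwd_seq", "rev_seq",
            "fwd_tail", "rev_tail")
  if (!all(need %in% colnames(mcols(amp))))
    return(paste("amplicons must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(mcols(amp)$id))
    msg <- c(msg, "amplicon ids must be unique")
  if (length(amp)) {
    ins_w <- width(amp) - mcols(amp)$fwd_len - mcols(amp)$rev_len
    if (any(ins_w <= 0))
      msg <- c(msg, "every amplicon insert span must be non-empty")
    bad <- setdiff(as.character(seqnames(amp)), names(object@reference))
    if (length(bad))
      msg <- c(msg, paste("amplicon contigs missing from reference:",
                          paste(bad, collapse = ",")))
  }
  tgt <- object@targets
  if (length(tgt) && !all(c("gene", "exon", "coding") %in%
                          colnames(mcols(tgt))))
    msg <- c(msg, "targets must carry gene, exon and coding columns")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Reads aligned to the panel reference
#'
#' One row per read, SAM-flavoured: alignment start (1-based), CIGAR over
#' the ops M (match/mismatch), I (insertion), D (deletion) and S (soft
#' clip), sequence and Phred+33 qualities always in reference orientation,
#' source amplicon and strand. \code{trimmed} records whether primer
#' footprints have been soft-clipped.
#'
#' @slot reads \code{data.frame} with columns \code{read_id},
#'   \code{amplicon}, \code{contig}, \code{start}, \code{cigar},
#'   \code{seq}, \code{qual}, \code{strand}, \code{status}.
#' @slot trimmed logical scalar.
#' @export
setClass("AlignedReads",
  representation(reads = "data.frame", trimmed = "logical")
)

setValidity("AlignedReads", function(object) {
  df <- object@reads
  need <- c("read_id", "amplicon", "contig", "start", "cigar", "seq",
            "qual", "strand", "status")
  if (!all(need %in% names(df)))
    return(paste("reads must have columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    qlen <- cigarReadLength(df$cigar)
    if (any(qlen != nchar(df$seq)))
      return("CIGAR read-consuming length must equal sequence length")
    if (any(nchar(df$seq) != nchar(df$qual)))
      return("sequence and quality strings must have equal length")
  }
  TRUE
})

#' aCGH probe log2-ratio track
#'
#' Ordered probe-level log2 ratios with an attached noise estimate (derivative
#' MAD) and any centralization shift already applied.
#'
#' @slot probes \code{data.frame} with columns \code{probe_id},
#'   \code{contig}, \code{pos}, \code{log2}, sorted by (contig, pos).
#' @slot noiseSd numeric scalar; \code{NA} until estimated.
#' @slot shift numeric scalar; total centralization shift applied so far.
#' @export
setClass("ProbeTrack",
  representation(probes = "data.frame", noiseSd = "numeric",
                 shift = "numeric")
)

setValidity("ProbeTrack", function(object) {
  df <- object@probes
  if (!all(c("probe_id", "contig", "pos", "log2") %in% names(df)))
    return("probes must have columns probe_id, contig, pos, log2")
  if (nrow(df)) {
    if (any(!is.finite(df$log2))) return("log2 ratios must be finite")
    o <- order(df$contig, df$pos)
    if (any(o != seq_len(nrow(df))))
      return("probes must be sorted by (contig, pos)")
  }
  TRUE
})
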