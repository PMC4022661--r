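# On-disk formats: reference FASTA (Biostrings), targets BED6
# (rtracklayer; name = gene|exon|coding), panel design as a tab-separated
# file with 0-based half-open outer coordinates (BED convention).

#' Read / write target exons as BED6
#'
#' The BED name field encodes \code{gene|exon|coding} where coding is 0/1.
#' BED is 0-based half-open on disk; in memory coordinates are 1-based
#' closed \code{GRanges}.
#' @param path file path.
#' @param targetExons \code{GRanges} with gene/exon/coding columns.
#' @return \code{readTargetsBed} returns a \code{GRanges}.
#' @export
readTargetsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(mcols(gr)$name, "|", fixed = TRUE)
  mcols(gr) <- DataFrame(
    gene = vapply(parts, `[`, character(1), 1L),
    exon = as.integer(vapply(parts, `[`, character(1), 2L)),
    coding = vapply(parts, `[`, character(1), 3L) == "1"
  )
  gr
}

#' @rdname readTargetsBed
#' @export
writeTargetsBed <- function(targetExons, path) {
  out <- granges(targetExons)
  mcols(out)$name <- paste(mcols(targetExons)$gene,
                           mcols(targetExons)$exon,
                           as.integer(mcols(targetExons)$coding),
                           sep = "|")
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read / write a panel design file
#'
#' Tab-separated with header; columns \code{id, contig, outer_start,
#' outer_end, fwd_len, rev_len, fwd_seq, rev_seq, fwd_tail, rev_tail}.
#' \code{outer_start}/\code{outer_end} are 0-based half-open on disk.
#'
#' @param path design file path.
#' @param reference \code{DNAStringSet} used to validate primer footprints.
#' @param design a \linkS4class{PanelDesign}.
#' @param ... passed to [panelDesign()].
#' @param targetExons targets to pair with the amplicons.
#' @return \code{readPanelDesign} returns a \linkS4class{PanelDesign}.
#' @export
readPanelDesign <- function(path, targetExons, reference, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "contig", "outer_start", "outer_end", "fwd_len",
            "rev_len", "fwd_seq", "rev_seq", "fwd_tail", "rev_tail")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  amp <- GRanges(df$contig,
                 IRanges(df$outer_start + 1L, df$outer_end))
  mcols(amp) <- DataFrame(df[, c("id", "fwd_len", "rev_len", "fwd_seq",
                                 "rev_seq", "fwd_tail", "rev_tail")])
  panelDesign(amp, targetExons, reference, ...)
}

#' @rdname readPanelDesign
#' @export
writePanelDesign <- function(design, path) {
  amp <- amplicons(design)
  df <- data.frame(
    id = mcols(amp)$id,
    contig = as.character(seqnames(amp)),
    outer_start = start(amp) - 1L,
    outer_end = end(amp),
    fwd_len = mcols(amp)$fwd_len, rev_len = mcols(amp)$rev_len,
    fwd_seq = mcols(amp)$fwd_seq, rev_seq = mcols(amp)$rev_seq,
    fwd_tail = mcols(amp)$fwd_tail, rev_tail = mcols(amp)$rev_tail,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
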