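# Minimal SAM emission so trimmed/untrimmed alignments can be inspected
# with standard viewers; soft clips use the standard S CIGAR op. Tests
# round-trip these files through Rsamtools as the independent format
# check.

#' Write alignments as SAM
#'
#' Sequences are stored in reference orientation, so records carry only
#' the 0/16 flag; fully clipped or otherwise unusable reads are emitted
#' as unmapped (flag 4). The source amplicon travels in the \code{XA} tag.
#'
#' @param aligned an \linkS4class{AlignedReads}.
#' @param reference \code{DNAStringSet} (for \code{@SQ} header lines).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSam <- function(aligned, reference, path) {
  df <- readRecords(aligned)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference)[i],
                       Biostrings::width(reference)[i]), con)
  writeLines(paste0("@PG\tID:ampliDx\tPN:ampliDx\tVN:",
                    as.character(utils::packageVersion("ampliDx"))), con)
  if (nrow(df)) {
    usable <- df$status == "aligned"
    flag <- ifelse(usable, ifelse(df$strand == "-", 16L, 0L), 4L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXA:Z:%s",
                     df$read_id, flag,
                     ifelse(usable, df$contig, "*"),
                     ifelse(usable, df$start, 0L),
                     ifelse(usable, 60L, 0L),
                     ifelse(usable, df$cigar, "*"),
                     df$seq, df$qual, df$amplicon)
    writeLines(lines, con)
  }
  invisible(path)
}
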