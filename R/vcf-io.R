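# VCF 4.2 emission for the candidate table. Tests read the file back with
# VariantAnnotation as the independent format check.

#' Write candidate variants as VCF 4.2
#'
#' INFO carries DP, AC, AF (allele ratio), TIER and PROTECTED; the FILTER
#' column carries the accumulated filter flags (PASS when clean).
#'
#' @param candidates data.frame from [callVariants()] /
#'   [filterPolymorphisms()].
#' @param reference \code{DNAStringSet} (contig header lines).
#' @param path output path.
#' @param sampleName sample identifier written in the header.
#' @return invisibly, \code{path}.
#' @export
writeVariantVcf <- function(candidates, reference, path,
                            sampleName = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=ampliDx_",
           as.character(utils::packageVersion("ampliDx"))),
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele ratio\">",
    paste0("##INFO=<ID=TIER,Number=1,Type=String,Description=",
           "\"Artifact-risk tier\">"),
    paste0("##INFO=<ID=PROTECTED,Number=0,Type=Flag,Description=",
           "\"Protected known causative variant\">"),
    paste0("##FILTER=<ID=LowAlleleCount,Description=",
           "\"Fewer supporting reads than the allele-count floor\">"),
    paste0("##FILTER=<ID=OffReportable,Description=",
           "\"Outside the reportable range\">"),
    paste0("##FILTER=<ID=CommonPolymorphism,Description=",
           "\"At or above the population-frequency cutoff\">"),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ), con)
  if (nrow(candidates)) {
    filt <- ifelse(nzchar(candidates$filters), candidates$filters, "PASS")
    info <- sprintf("DP=%d;AC=%d;AF=%.6g;TIER=%s%s",
                    candidates$depth, candidates$alt_count,
                    candidates$allele_ratio, candidates$risk_tier,
                    ifelse(candidates$protected, ";PROTECTED", ""))
    qual <- ifelse(is.na(candidates$mean_alt_qual), ".",
                   sprintf("%.1f", candidates$mean_alt_qual))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                       candidates$contig, candidates$pos, candidates$ref,
                       candidates$alt, qual, filt, info), con)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' Used for the no/low coverage report. BED is 0-based half-open.
#' @param gr \code{GRanges}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBedIntervals <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
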