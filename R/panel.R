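#' Construct a PanelDesign
#'
#' Assembles amplicons, target exons and the reference into a validated
#' \linkS4class{PanelDesign}. The reportable range is derived from the
#' coding exons with \code{flank} bases of intronic sequence on each side
#' (merged where flanks touch). Amplicon lengths outside \code{lenBounds}
#' raise a warning, not an error: out-of-bounds amplicons are a design
#' smell, not a structural fault.
#'
#' @param amplicons \code{GRanges} with the metadata columns documented in
#'   \linkS4class{PanelDesign}.
#' @param targetExons \code{GRanges} with \code{gene}, \code{exon},
#'   \code{coding} metadata columns; exons of one gene must be
#'   non-overlapping.
#' @param reference \code{DNAStringSet}, one entry per contig.
#' @param flank integer, reporting flank in bases (default 5).
#' @param lenBounds length-2 integer vector of soft amplicon length bounds.
#' @param checkPrimers verify primer footprints against the reference
#'   (forward primer must equal the reference at its footprint, reverse
#'   primer the reverse complement).
#' @return A \linkS4class{PanelDesign}.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100),
#'   collapse = "")))
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 180),
#'   gene = "G1", exon = 1L, coding = TRUE)
#' @export
panelDesign <- function(amplicons, targetExons, reference, flank = 5L,
                        lenBounds = c(110L, 199L), checkPrimers = TRUE) {
  stopifnot(is(amplicons, "GRanges"), is(targetExons, "GRanges"),
            is(reference, "DNAStringSet"))
  checkExonLayout(targetExons)
  reportable <- buildReportableRange(targetExons, flank = flank)
  obj <- new("PanelDesign", amplicons = amplicons, targets = targetExons,
             reportable = reportable, reference = reference)
  if (length(amplicons)) {
    w <- width(amplicons)
    if (any(w < lenBounds[1] | w > lenBounds[2]))
      warning(sum(w < lenBounds[1] | w > lenBounds[2]),
              " amplicon(s) outside the length bounds ",
              lenBounds[1], "-", lenBounds[2], " bp")
    if (checkPrimers) checkPrimerFootprints(obj)
  }
  obj
}

checkExonLayout <- function(targetExons) {
  for (g in unique(mcols(targetExons)$gene)) {
    ex <- targetExons[mcols(targetExons)$gene == g]
    ex <- BiocGenerics::sort(ex)
    if (length(ex) > 1 &&
        any(start(ex)[-1] <= end(ex)[-length(ex)] &
            as.character(seqnames(ex))[-1] ==
              as.character(seqnames(ex))[-length(ex)]))
      stop("exons of gene ", g, " overlap")
  }
  invisible(TRUE)
}

checkPrimerFootprints <- function(design) {
  amp <- amplicons(design)
  ref <- refSequence(design)
  for (i in seq_along(amp)) {
    ctg <- as.character(seqnames(amp))[i]
    fl <- mcols(amp)$fwd_len[i]; rl <- mcols(amp)$rev_len[i]
    fwd_ref <- as.character(subseq(ref[[ctg]], start(amp)[i],
                                   start(amp)[i] + fl - 1L))
    rev_ref <- as.character(reverseComplement(
      subseq(ref[[ctg]], end(amp)[i] - rl + 1L, end(amp)[i])))
    if (fwd_ref != mcols(amp)$fwd_seq[i])
      stop("amplicon ", mcols(amp)$id[i],
           ": forward primer does not match the reference footprint")
    if (rev_ref != mcols(amp)$rev_seq[i])
      stop("amplicon ", mcols(amp)$id[i],
           ": reverse primer does not match the reference footprint")
  }
  invisible(TRUE)
}

#' Insert spans of a panel's amplicons
#'
#' The insert is the sample-derived portion between the two primer
#' footprints.
#' @param design a \linkS4class{PanelDesign} or the amplicon \code{GRanges}.
#' @return \code{GRanges} of insert spans, same order and ids.
#' @export
ampliconInserts <- function(design) {
  amp <- if (is(design, "PanelDesign")) amplicons(design) else design
  if (!length(amp)) return(amp)
  ins <- GRanges(seqnames(amp),
                 IRanges(start(amp) + mcols(amp)$fwd_len,
                         end(amp) - mcols(amp)$rev_len))
  mcols(ins)$id <- mcols(amp)$id
  ins
}

#' Primer footprints of a panel's amplicons
#'
#' @param design a \linkS4class{PanelDesign} or the amplicon \code{GRanges}.
#' @return \code{GRanges} with two ranges per amplicon (metadata columns
#'   \code{id} and \code{side} in \code{fwd}/\code{rev}).
#' @export
primerFootprints <- function(design) {
  amp <- if (is(design, "PanelDesign")) amplicons(design) else design
  if (!length(amp)) return(GRanges())
  fwd <- GRanges(seqnames(amp),
                 IRanges(start(amp), width = mcols(amp)$fwd_len))
  rev <- GRanges(seqnames(amp),
                 IRanges(end(amp) - mcols(amp)$rev_len + 1L, end(amp)))
  mcols(fwd) <- DataFrame(id = mcols(amp)$id, side = "fwd")
  mcols(rev) <- DataFrame(id = mcols(amp)$id, side = "rev")
  c(fwd, rev)
}

#' Build the reportable range from target exons
#'
#' Coding exons are each extended by \code{flank} intronic bases on both
#' sides and merged; non-coding exons are excluded. Variants are reported
#' only within this range.
#'
#' @param targetExons \code{GRanges} with a logical \code{coding} column.
#' @param flank non-negative integer (default 5).
#' @return \code{GRanges} of merged, non-overlapping intervals; total width
#'   is \code{sum(width(...))}.
#' @export
buildReportableRange <- function(targetExons, flank = 5L) {
  stopifnot(flank >= 0)
  if (!length(targetExons)) stop("no target exons supplied")
  coding <- targetExons[mcols(targetExons)$coding]
  if (!length(coding)) stop("no coding exons among the targets")
  ext <- GRanges(seqnames(coding),
                 IRanges(pmax(1L, start(coding) - as.integer(flank)),
                         end(coding) + as.integer(flank)))
  reduce(BiocGenerics::sort(ext))
}

#' Per-base amplicon insert redundancy over the reportable range
#'
#' Counts, for every reportable base, how many amplicon inserts cover it.
#' Bases covered by no insert are gaps (the panel cannot report them);
#' bases covered by exactly one insert are drop-out-prone (a polymorphism
#' under that single amplicon's primer silently removes one allele).
#'
#' @param design a \linkS4class{PanelDesign}.
#' @return list with \code{coverage} (data.frame contig/pos/n_inserts),
#'   \code{gaps} and \code{dropout_prone} (\code{GRanges} of merged runs),
#'   and \code{histogram} (table of redundancy counts).
#' @export
insertCoverage <- function(design) {
  stopifnot(is(design, "PanelDesign"))
  rep_gr <- reportableRange(design)
  ins <- ampliconInserts(design)
  pos <- unlist(lapply(seq_along(rep_gr), function(i)
    start(rep_gr)[i]:end(rep_gr)[i]))
  ctg <- rep(as.character(seqnames(rep_gr)), width(rep_gr))
  base_gr <- GRanges(ctg, IRanges(pos, pos))
  n <- countOverlapsSafe(base_gr, ins)
  cov <- data.frame(contig = ctg, pos = pos, n_inserts = n,
                    stringsAsFactors = FALSE)
  list(
    coverage = cov,
    gaps = reduce(base_gr[n == 0L]),
    dropout_prone = reduce(base_gr[n == 1L]),
    histogram = table(n)
  )
}

countOverlapsSafe <- function(query, subject) {
  if (!length(subject)) return(integer(length(query)) * 0L)
  GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE)
}

#' Validate panel completeness
#'
#' A complete panel has every reportable base covered by at least one
#' amplicon insert. Fails with a diagnostic naming the uncovered
#' interval(s) otherwise.
#'
#' @param design a \linkS4class{PanelDesign}.
#' @return \code{TRUE} invisibly on success.
#' @export
validatePanelDesign <- function(design) {
  validObject(design)
  cov <- insertCoverage(design)
  if (length(cov$gaps)) {
    gapstr <- paste0(seqnames(cov$gaps), ":", start(cov$gaps), "-",
                     end(cov$gaps), collapse = ", ")
    stop("panel has uncovered reportable bases: ", gapstr)
  }
  invisible(TRUE)
}

#' Positions colliding with primer footprints
#'
#' Checks candidate variant positions (e.g. known SNPs) against every
#' primer footprint; a polymorphism under a primer disrupts hybridization
#' and can cause allele drop-out for that amplicon.
#'
#' @param design a \linkS4class{PanelDesign}.
#' @param variantPositions \code{GRanges} of 1-bp positions, or a
#'   data.frame with \code{contig} and \code{pos}.
#' @return data.frame with columns \code{amplicon}, \code{side},
#'   \code{contig}, \code{pos}; zero rows when nothing collides.
#' @export
checkPrimerVariantOverlap <- function(design, variantPositions) {
  if (is.data.frame(variantPositions))
    variantPositions <- GRanges(variantPositions$contig,
                                IRanges(variantPositions$pos,
                                        variantPositions$pos))
  fp <- primerFootprints(design)
  if (!length(fp) || !length(variantPositions))
    return(data.frame(amplicon = character(), side = character(),
                      contig = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  hits <- findOverlaps(variantPositions, fp, ignore.strand = TRUE)
  data.frame(
    amplicon = mcols(fp)$id[S4Vectors::subjectHits(hits)],
    side = mcols(fp)$side[S4Vectors::subjectHits(hits)],
    contig = as.character(seqnames(variantPositions))[
      S4Vectors::queryHits(hits)],
    pos = start(variantPositions)[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Panel design summary statistics
#'
#' @param design a \linkS4class{PanelDesign}.
#' @return list with \code{n_amplicons}, \code{min_len}, \code{max_len},
#'   \code{mean_len} (outer span lengths) and \code{redundancy} (insert
#'   redundancy histogram over the reportable range; \code{NULL} for an
#'   empty design).
#' @export
designStats <- function(design) {
  amp <- amplicons(design)
  if (!length(amp))
    return(list(n_amplicons = 0L, min_len = NA_integer_,
                max_len = NA_integer_, mean_len = NA_real_,
                redundancy = NULL))
  w <- width(amp)
  list(n_amplicons = length(amp), min_len = min(w), max_len = max(w),
       mean_len = mean(w), redundancy = insertCoverage(design)$histogram)
}
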