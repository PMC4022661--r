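# Quality-aware pileup over the reportable range and the clinical filter
# chain: allele-count threshold, low-coverage flagging, artifact-risk
# tiers, common-polymorphism removal and the Sanger confirmation worklist.

#' Variant-calling filter configuration
#'
#' Defaults follow the assay's clinical settings: bases below Phred 20
#' are excluded from pileup counts, a variant needs at least 50 supporting
#' reads, bases at or under 50x coverage are flagged for orthogonal
#' sequencing, and calls with allele ratio under 0.2 are routed to a
#' review tier (not discarded: true mosaics and trimming-rescued calls
#' live there).
#'
#' @param minBaseQual minimum Phred base quality counted in pileup.
#' @param minAltReads minimum variant-supporting reads to emit a call.
#' @param lowCovThreshold flag bases with depth <= this (inclusive).
#' @param lowRatioCutoff allele ratios below this go to the review tier.
#' @param polymorphismFreqCutoff population frequency at or above which an
#'   unprotected variant is filtered as a common polymorphism.
#' @param protectedVariants character vector of variant keys
#'   (\code{"contig:pos:ref>alt"}, 1-based) exempt from filtering, e.g.
#'   known causative mutations.
#' @return list of class \code{FilterConfig}.
#' @export
filterConfig <- function(minBaseQual = 20L, minAltReads = 50L,
                         lowCovThreshold = 50L, lowRatioCutoff = 0.2,
                         polymorphismFreqCutoff = 0.01,
                         protectedVariants = character()) {
  stopifnot(minBaseQual >= 0, minAltReads >= 0, lowCovThreshold >= 0,
            lowRatioCutoff >= 0, polymorphismFreqCutoff >= 0)
  structure(list(minBaseQual = as.integer(minBaseQual),
                 minAltReads = as.integer(minAltReads),
                 lowCovThreshold = as.integer(lowCovThreshold),
                 lowRatioCutoff = lowRatioCutoff,
                 polymorphismFreqCutoff = polymorphismFreqCutoff,
                 protectedVariants = protectedVariants),
            class = "FilterConfig")
}

variantKey <- function(contig, pos, ref, alt) {
  paste0(contig, ":", pos, ":", ref, ">", alt)
}

#' Quality-filtered pileup over a region
#'
#' One column per base of \code{region}: allele counts (A/C/G/T plus the
#' deletion allele) restricted to non-soft-clipped bases with quality at
#' or above \code{minBaseQual}; column depth is the sum of its allele
#' counts. Insertions are keyed to their left-flanking column and
#' deletions to their span, reported as separate event tables.
#'
#' @param aligned an \linkS4class{AlignedReads} (normally trimmed).
#' @param region \code{GRanges} of the interval(s) to pile up, e.g. the
#'   reportable range.
#' @param config a \code{FilterConfig}.
#' @return list of class \code{Pileup} with \code{columns} (data.frame:
#'   contig, pos, depth, A, C, G, T, N, DEL and per-allele mean quality
#'   columns qA..qT), \code{insertions} (contig, pos, seq, count,
#'   mean_qual) and \code{deletions} (contig, pos, len, count).
#' @export
pileupReads <- function(aligned, region, config = filterConfig()) {
  stopifnot(is(aligned, "AlignedReads"), is(region, "GRanges"))
  df <- readRecords(aligned)
  df <- df[df$status == "aligned", , drop = FALSE]
  cols <- list(); insl <- list(); dell <- list()
  for (i in seq_along(region)) {
    ctg <- as.character(seqnames(region))[i]
    ws <- start(region)[i]; we <- end(region)[i]
    sub <- df[df$contig == ctg & df$start <= we, , drop = FALSE]
    if (nrow(sub)) {
      ends <- sub$start + cigarRefLength(sub$cigar) - 1L
      sub <- sub[ends >= ws, , drop = FALSE]
    }
    if (nrow(sub)) {
      pc <- .pileupCore(as.integer(sub$start), sub$cigar, sub$seq,
                        sub$qual, config$minBaseQual,
                        as.integer(ws), as.integer(we))
    } else {
      pc <- list(counts = matrix(0L, 6, we - ws + 1L),
                 qsum = matrix(0, 5, we - ws + 1L),
                 ins = data.frame(pos = numeric(), seq = character(),
                                  count = integer(),
                                  mean_qual = numeric()),
                 del = data.frame(pos = numeric(), len = integer(),
                                  count = integer()))
    }
    cnt <- t(pc$counts)
    colnames(cnt) <- c("A", "C", "G", "T", "N", "DEL")
    qs <- t(pc$qsum)
    qmean <- qs[, 1:4, drop = FALSE] /
      pmax(1L, cnt[, 1:4, drop = FALSE])
    colnames(qmean) <- paste0("q", c("A", "C", "G", "T"))
    cols[[i]] <- data.frame(contig = ctg, pos = ws:we,
                            depth = rowSums(cnt), cnt, qmean,
                            stringsAsFactors = FALSE)
    if (nrow(pc$ins))
      insl[[i]] <- data.frame(contig = ctg, pc$ins,
                              stringsAsFactors = FALSE)
    if (nrow(pc$del))
      dell[[i]] <- data.frame(contig = ctg, pc$del,
                              stringsAsFactors = FALSE)
  }
  structure(list(
    columns = do.call(rbind, c(cols, list(make.row.names = FALSE))),
    insertions = if (length(insl))
      do.call(rbind, c(insl, list(make.row.names = FALSE)))
    else data.frame(contig = character(), pos = numeric(),
                    seq = character(), count = integer(),
                    mean_qual = numeric(), stringsAsFactors = FALSE),
    deletions = if (length(dell))
      do.call(rbind, c(dell, list(make.row.names = FALSE)))
    else data.frame(contig = character(), pos = numeric(),
                    len = integer(), count = integer(),
                    stringsAsFactors = FALSE)),
    class = "Pileup")
}

#' Call candidate variants from a pileup
#'
#' Emits every non-reference allele supported by at least
#' \code{minAltReads} quality-passing reads; alleles below the threshold
#' are still emitted when they match \code{protectedVariants} (flagged
#' \code{protected}). Calls with allele ratio below \code{lowRatioCutoff}
#' are assigned the \code{low_ratio_review} risk tier -- the profile of
#' most sequencing artifacts, but also of true mosaics, so they are routed
#' to confirmation rather than discarded. Positions are 1-based;
#' insertions/deletions are reported left-anchored VCF-style.
#'
#' @param pile a \code{Pileup} from [pileupReads()].
#' @param reference \code{DNAStringSet}.
#' @param config a \code{FilterConfig}.
#' @param reportable optional \code{GRanges}; candidates outside it get
#'   the \code{OffReportable} filter.
#' @return data.frame with columns \code{contig, pos, ref, alt, depth,
#'   alt_count, allele_ratio, mean_alt_qual, risk_tier, protected,
#'   filters, key}.
#' @export
callVariants <- function(pile, reference, config = filterConfig(),
                         reportable = NULL) {
  stopifnot(inherits(pile, "Pileup"))
  out <- list()
  cc <- pile$columns
  if (!is.null(cc) && nrow(cc)) {
    refbase <- vapply(seq_len(nrow(cc)), function(i)
      as.character(subseq(reference[[cc$contig[i]]], cc$pos[i],
                          cc$pos[i])), character(1))
    for (alt in c("A", "C", "G", "T")) {
      sel <- which(cc[[alt]] > 0L & refbase != alt)
      for (s in sel) {
        out[[length(out) + 1L]] <- data.frame(
          contig = cc$contig[s], pos = cc$pos[s], ref = refbase[s],
          alt = alt, depth = cc$depth[s], alt_count = cc[[alt]][s],
          mean_alt_qual = cc[[paste0("q", alt)]][s],
          stringsAsFactors = FALSE)
      }
    }
  }
  ins <- pile$insertions
  if (nrow(ins)) {
    for (s in seq_len(nrow(ins))) {
      anchor <- as.character(subseq(reference[[ins$contig[s]]],
                                    ins$pos[s], ins$pos[s]))
      d <- columnDepth(cc, ins$contig[s], ins$pos[s])
      out[[length(out) + 1L]] <- data.frame(
        contig = ins$contig[s], pos = ins$pos[s], ref = anchor,
        alt = paste0(anchor, ins$seq[s]), depth = d,
        alt_count = ins$count[s], mean_alt_qual = ins$mean_qual[s],
        stringsAsFactors = FALSE)
    }
  }
  del <- pile$deletions
  if (nrow(del)) {
    for (s in seq_len(nrow(del))) {
      apos <- del$pos[s] - 1L
      refseq <- as.character(subseq(reference[[del$contig[s]]], apos,
                                    del$pos[s] + del$len[s] - 1L))
      d <- columnDepth(cc, del$contig[s], del$pos[s])
      out[[length(out) + 1L]] <- data.frame(
        contig = del$contig[s], pos = apos,
        ref = refseq, alt = substr(refseq, 1L, 1L), depth = d,
        alt_count = del$count[s], mean_alt_qual = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(emptyCandidates())
  cand <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  cand$allele_ratio <- cand$alt_count / pmax(1L, cand$depth)
  cand$key <- variantKey(cand$contig, cand$pos, cand$ref, cand$alt)
  cand$protected <- cand$key %in% config$protectedVariants
  keep <- cand$alt_count >= config$minAltReads | cand$protected
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(emptyCandidates())
  cand$risk_tier <- ifelse(cand$allele_ratio < config$lowRatioCutoff,
                           "low_ratio_review", "standard")
  cand$filters <- ifelse(cand$alt_count < config$minAltReads,
                         "LowAlleleCount", "")
  if (!is.null(reportable)) {
    cgr <- GRanges(cand$contig,
                   IRanges(cand$pos, cand$pos + nchar(cand$ref) - 1L))
    off <- !overlapsAny(cgr, reportable, ignore.strand = TRUE)
    cand$filters <- paste0(cand$filters,
                           ifelse(off & nzchar(cand$filters), ";", ""),
                           ifelse(off, "OffReportable", ""))
  }
  cand <- cand[order(cand$contig, cand$pos, cand$alt), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

columnDepth <- function(cc, contig, pos) {
  i <- which(cc$contig == contig & cc$pos == pos)
  if (length(i)) cc$depth[i[1]] else 0L
}

emptyCandidates <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), alt_count = integer(),
             mean_alt_qual = numeric(), allele_ratio = numeric(),
             key = character(), protected = logical(),
             risk_tier = character(), filters = character(),
             stringsAsFactors = FALSE)
}

#' Flag no/low coverage intervals
#'
#' Maximal merged runs of consecutive reportable bases whose pileup depth
#' is at or below the threshold (inclusive: a base at exactly the
#' threshold is flagged). These regions go to orthogonal sequencing.
#'
#' @param pile a \code{Pileup}.
#' @param config a \code{FilterConfig}.
#' @return \code{GRanges} of flagged intervals with a \code{min_depth}
#'   metadata column.
#' @export
flagLowCoverage <- function(pile, config = filterConfig()) {
  cc <- pile$columns
  if (is.null(cc) || !nrow(cc)) return(GRanges())
  low <- cc[cc$depth <= config$lowCovThreshold, , drop = FALSE]
  if (!nrow(low)) return(GRanges())
  gr <- reduce(GRanges(low$contig, IRanges(low$pos, low$pos)))
  mind <- vapply(seq_along(gr), function(i) {
    sel <- cc$contig == as.character(seqnames(gr))[i] &
      cc$pos >= start(gr)[i] & cc$pos <= end(gr)[i]
    min(cc$depth[sel])
  }, numeric(1))
  mcols(gr)$min_depth <- mind
  gr
}

#' Remove common polymorphisms from the candidate list
#'
#' Candidates whose key appears in \code{freqTable} at or above the
#' frequency cutoff receive the \code{CommonPolymorphism} filter and are
#' excluded from the reportable set -- unless protected. Protected
#' candidates are also retained when flagged \code{OffReportable} (known
#' causative variants outside the reportable range stay reportable).
#'
#' @param candidates data.frame from [callVariants()].
#' @param freqTable named numeric vector mapping variant keys to
#'   population frequencies (absent keys count as frequency 0).
#' @param config a \code{FilterConfig}.
#' @return the candidate data.frame with updated \code{filters} and an
#'   added logical \code{reportable} column.
#' @export
filterPolymorphisms <- function(candidates, freqTable = numeric(),
                                config = filterConfig()) {
  if (!nrow(candidates)) {
    candidates$reportable <- logical(0)
    return(candidates)
  }
  freq <- freqTable[candidates$key]
  freq[is.na(freq)] <- 0
  common <- freq >= config$polymorphismFreqCutoff & !candidates$protected
  candidates$filters <- paste0(
    candidates$filters,
    ifelse(common & nzchar(candidates$filters), ";", ""),
    ifelse(common, "CommonPolymorphism", ""))
  off <- grepl("OffReportable", candidates$filters)
  candidates$reportable <- !common & (!off | candidates$protected)
  candidates
}

#' Confirmation worklist
#'
#' One record per distinct reportable variant and per low-coverage
#' interval, in stable (contig, position) order: everything an orthogonal
#' confirmation assay must cover.
#'
#' @param reportables candidate data.frame (rows with
#'   \code{reportable == TRUE} are used, or all rows if the column is
#'   absent).
#' @param lowCovIntervals \code{GRanges} from [flagLowCoverage()].
#' @return data.frame with \code{type} (variant/low_coverage),
#'   \code{contig, start, end, key}.
#' @export
confirmationWorklist <- function(reportables, lowCovIntervals = GRanges()) {
  rows <- list()
  if (nrow(reportables)) {
    use <- if ("reportable" %in% names(reportables))
      reportables[reportables$reportable, , drop = FALSE]
    else reportables
    if (nrow(use))
      rows[[1L]] <- data.frame(
        type = "variant", contig = use$contig, start = use$pos,
        end = use$pos + nchar(use$ref) - 1L, key = use$key,
        stringsAsFactors = FALSE)
  }
  if (length(lowCovIntervals))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "low_coverage",
      contig = as.character(seqnames(lowCovIntervals)),
      start = start(lowCovIntervals), end = end(lowCovIntervals),
      key = paste0(seqnames(lowCovIntervals), ":",
                   start(lowCovIntervals), "-", end(lowCovIntervals)),
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(type = character(), contig = character(),
                      start = integer(), end = integer(),
                      key = character(), stringsAsFactors = FALSE))
  wl <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wl <- wl[!duplicated(wl$key), , drop = FALSE]
  wl <- wl[order(wl$contig, wl$start, wl$type, wl$key), , drop = FALSE]
  rownames(wl) <- NULL
  wl
}
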