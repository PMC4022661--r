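# Read-to-amplicon assignment, primer-anchored banded alignment, and
# primer soft-clip trimming with alignment-coordinate reconstruction.

#' Assign reads to amplicons by primer prefix
#'
#' Each read is matched at its start against every amplicon's expected
#' prefix: the forward or reverse primer as synthesized, optionally
#' preceded by the adapter tail. The amplicon with the fewest prefix
#' mismatches wins, provided it has at most \code{maxMismatch}; ties break
#' to the lexicographically smallest amplicon id. Reads matching no
#' amplicon are unassigned.
#'
#' @param reads data.frame with \code{read_id}, \code{seq} (and
#'   \code{qual}) columns, e.g. from [simulateReads()] or
#'   [readReadsFastq()].
#' @param design a \linkS4class{PanelDesign}.
#' @param maxMismatch maximum substitutions tolerated in the prefix
#'   (default 2).
#' @return data.frame with \code{read_id, amplicon, strand, mismatches,
#'   clip5} (adapter-tail bases to clip before the primer); unassigned
#'   reads have \code{amplicon = NA}.
#' @export
assignReads <- function(reads, design, maxMismatch = 2L) {
  stopifnot(maxMismatch >= 0)
  amp <- amplicons(design)
  cand <- assignCandidates(amp)
  res <- data.frame(read_id = reads$read_id,
                    amplicon = NA_character_, strand = NA_character_,
                    mismatches = NA_integer_, clip5 = 0L,
                    stringsAsFactors = FALSE)
  if (!nrow(reads) || !nrow(cand)) return(res)
  # exact-prefix dictionary per candidate length, then mismatch rescue
  todo <- rep(TRUE, nrow(reads))
  for (L in sort(unique(cand$len))) {
    cl <- cand[cand$len == L, , drop = FALSE]
    cl <- cl[order(cl$id), , drop = FALSE]      # lexicographic tie-break
    key <- substr(reads$seq, 1L, L)
    m <- match(key, cl$prefix)
    hit <- which(!is.na(m) & todo)
    if (length(hit)) {
      res$amplicon[hit] <- cl$id[m[hit]]
      res$strand[hit] <- cl$strand[m[hit]]
      res$mismatches[hit] <- 0L
      res$clip5[hit] <- cl$tail_len[m[hit]]
      todo[hit] <- FALSE
    }
  }
  for (r in which(todo)) {
    rv <- utf8ToInt(reads$seq[r])
    best <- Inf; bid <- NA_character_; bstrand <- NA_character_
    bclip <- 0L
    for (k in seq_len(nrow(cand))) {
      L <- cand$len[k]
      if (length(rv) < L) next
      mm <- sum(rv[seq_len(L)] != cand$pref_int[[k]])
      better <- mm < best ||
        (mm == best && !is.na(bid) && cand$id[k] < bid)
      if (mm <= maxMismatch && better) {
        best <- mm; bid <- cand$id[k]; bstrand <- cand$strand[k]
        bclip <- cand$tail_len[k]
      }
    }
    if (!is.na(bid)) {
      res$amplicon[r] <- bid; res$strand[r] <- bstrand
      res$mismatches[r] <- as.integer(best); res$clip5[r] <- bclip
    }
  }
  res
}

assignCandidates <- function(amp) {
  if (!length(amp))
    return(data.frame(id = character(), strand = character(),
                      prefix = character(), len = integer(),
                      tail_len = integer(), stringsAsFactors = FALSE))
  mk <- function(id, strand, primer, tail) {
    rbind(
      data.frame(id = id, strand = strand, prefix = primer,
                 len = nchar(primer), tail_len = 0L,
                 stringsAsFactors = FALSE),
      data.frame(id = id, strand = strand,
                 prefix = paste0(tail, primer),
                 len = nchar(tail) + nchar(primer),
                 tail_len = nchar(tail), stringsAsFactors = FALSE))
  }
  parts <- lapply(seq_along(amp), function(i) rbind(
    mk(mcols(amp)$id[i], "+", mcols(amp)$fwd_seq[i],
       mcols(amp)$fwd_tail[i]),
    mk(mcols(amp)$id[i], "-", mcols(amp)$rev_seq[i],
       mcols(amp)$rev_tail[i])))
  cand <- do.call(rbind, parts)
  cand$pref_int <- lapply(cand$prefix, utf8ToInt)
  cand
}

#' Fraction of reads assigned to any amplicon
#'
#' @param assignments result of [assignReads()].
#' @return on-target fraction in [0, 1].
#' @export
onTargetRate <- function(assignments) {
  if (!nrow(assignments)) stop("no reads")
  mean(!is.na(assignments$amplicon))
}

# find where the 3' adapter starts in a read (read orientation); returns
# number of trailing bases to clip (0 if absent). Seeded by an exact match
# of the adapter's first 10 bases.
clip3Adapter <- function(seq, adapter) {
  sd <- substr(adapter, 1L, min(10L, nchar(adapter)))
  p <- regexpr(sd, seq, fixed = TRUE)
  if (p > 0L) nchar(seq) - as.integer(p) + 1L else 0L
}

#' Align assigned reads to the reference, primer-anchored
#'
#' Each assigned read is globally aligned (banded Needleman-Wunsch, linear
#' gap penalty) against its amplicon's reference span, anchored at the
#' primer end it starts from; indels are then shifted to their left-most
#' equivalent placement. Adapter-tail prefixes and 3' adapter read-through
#' become soft clips. The returned alignments are untrimmed: primer bases
#' are ordinary M ops.
#'
#' @param reads data.frame of reads (read_id, seq, qual).
#' @param assignments result of [assignReads()] for the same reads.
#' @param design a \linkS4class{PanelDesign}.
#' @param band half-width of the alignment band; must be at least the
#'   largest expected indel.
#' @param scoreParams list with \code{match}, \code{mismatch}, affine gap
#'   costs \code{gapOpen}/\code{gapExt} and \code{minFrac}: alignments
#'   scoring below \code{minFrac * match * aligned_length} are discarded.
#' @return list with \code{aligned} (an untrimmed
#'   \linkS4class{AlignedReads}) and \code{rejects} (data.frame of
#'   read_id, reason) covering unassigned and low-scoring reads.
#' @export
alignReads <- function(reads, assignments, design, band = 12L,
                       scoreParams = list(match = 1, mismatch = -1,
                                          gapOpen = -3, gapExt = -1,
                                          minFrac = 0.4)) {
  amp <- amplicons(design)
  ref <- refSequence(design)
  aid <- mcols(amp)$id
  actg <- as.character(seqnames(amp))
  astart <- start(amp); aend <- end(amp)
  awin <- vapply(seq_along(amp), function(i)
    as.character(subseq(ref[[actg[i]]], astart[i], aend[i])),
    character(1))
  adap_fwd <- vapply(mcols(amp)$rev_tail, revcompChr, character(1))
  adap_rev <- vapply(mcols(amp)$fwd_tail, revcompChr, character(1))
  idx <- match(assignments$amplicon, aid)
  n <- nrow(reads)
  o_start <- integer(n); o_cigar <- character(n)
  o_seq <- character(n); o_qual <- character(n)
  reason <- character(n)  # "" = aligned
  reason[is.na(idx)] <- "unassigned"
  todo <- which(!is.na(idx))
  # cache alignments of identical (amplicon, strand, clipped seq)
  cache <- new.env(parent = emptyenv())
  for (r in todo) {
    i <- idx[r]
    strand <- assignments$strand[r]
    clip5 <- assignments$clip5[r]
    sq <- reads$seq[r]; ql <- reads$qual[r]
    body <- if (clip5 > 0L) substr(sq, clip5 + 1L, nchar(sq)) else sq
    adapter <- if (strand == "+") adap_fwd[i] else adap_rev[i]
    clip3 <- clip3Adapter(body, adapter)
    core <- if (clip3 > 0L)
      substr(body, 1L, nchar(body) - clip3) else body
    if (!nchar(core)) { reason[r] <- "no_aligned_bases"; next }
    ckey <- paste(i, strand, core, sep = "\r")
    hitA <- cache[[ckey]]
    if (is.null(hitA)) {
      hitA <- alignAnchored(core, awin[i], strand, band, scoreParams,
                            ext = adapter)
      cache[[ckey]] <- hitA
    }
    if (is.null(hitA$op)) { reason[r] <- hitA$reason; next }
    op <- hitA$op; len <- hitA$len
    # attach the adapter clips in reference orientation
    if (strand == "+") {
      if (clip5 > 0L) { op <- c("S", op); len <- c(clip5, len) }
      if (clip3 > 0L) { op <- c(op, "S"); len <- c(len, clip3) }
      o_seq[r] <- sq; o_qual[r] <- ql
    } else {
      if (clip3 > 0L) { op <- c("S", op); len <- c(clip3, len) }
      if (clip5 > 0L) { op <- c(op, "S"); len <- c(len, clip5) }
      o_seq[r] <- revcompChr(sq)
      o_qual[r] <- revStr(ql)
    }
    o_start[r] <- astart[i] + hitA$ref_offset
    o_cigar[r] <- cigarBuild(op, len)
  }
  good <- which(!nzchar(reason) & !is.na(idx))
  df <- data.frame(read_id = assignments$read_id[good],
                   amplicon = aid[idx[good]], contig = actg[idx[good]],
                   start = o_start[good], cigar = o_cigar[good],
                   seq = o_seq[good], qual = o_qual[good],
                   strand = assignments$strand[good],
                   status = "aligned", stringsAsFactors = FALSE)
  bad <- which(nzchar(reason))
  rejects <- data.frame(read_id = assignments$read_id[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  list(aligned = new("AlignedReads", reads = df, trimmed = FALSE),
       rejects = rejects)
}

# core alignment of an oriented read body against the amplicon reference
# window; returns ops in reference orientation with ref_offset = offset of
# the first consumed reference base within the window (0-based). `ext` is
# the adapter continuation past the window's far end (in the read's own
# orientation): appending it lets read-through bases align exactly, after
# which everything placed beyond the true window is soft-clipped.
alignAnchored <- function(core, refwin, strand, band, sp, ext = "") {
  n <- nchar(core); m <- nchar(refwin)
  if (strand == "+") {
    qseq <- core; wseq <- paste0(refwin, ext)
  } else {
    # right-anchor by reversing both the reference-oriented read and the
    # window, then flipping the result back; the adapter continuation
    # (which precedes the window in reference orientation) lands at the
    # reversed window's end
    qseq <- revStr(revcompChr(core))
    wseq <- paste0(revStr(refwin), revStr(revcompChr(ext)))
  }
  mext <- nchar(wseq)
  bandUse <- max(band, n - mext + 4L)
  # fast path: perfect prefix fit needs no dynamic programming
  if (n <= mext && substr(wseq, 1L, n) == qseq) {
    ed <- list(op = "M", len = n, score = n * sp$match, ref_used = n)
    return(finishAlignment(ed, qseq, wseq, strand, m, n, sp))
  }
  ed <- .nwBandAlign(qseq, wseq, as.integer(bandUse), sp$match,
                     sp$mismatch, sp$gapOpen, sp$gapExt)
  finishAlignment(ed, qseq, wseq, strand, m, n, sp)
}

finishAlignment <- function(ed, qseq, wseq, strand, m, n, sp) {
  alen <- sum(ed$len[ed$op == "M"])
  if (ed$score < sp$minFrac * sp$match * n || alen == 0L)
    return(list(op = NULL, reason = "low_score"))
  op <- as.character(ed$op); len <- as.integer(ed$len)
  # read bases aligned beyond the true window (adapter read-through)
  # become soft clips; deletions out there are dropped
  over <- cumsum(ifelse(op %in% c("M", "D"), len, 0L))
  if (any(over > m)) {
    k <- match(TRUE, over > m)
    excess <- over[k] - m
    tail_op <- character(0); tail_len <- integer(0)
    if (op[k] == "M" && len[k] > excess) {
      tail_op <- "M"; tail_len <- len[k] - excess
    } else if (op[k] == "D" && len[k] > excess) {
      tail_op <- "D"; tail_len <- len[k] - excess
    }
    clipped <- op[k:length(op)]
    cliplen <- len[k:length(op)]
    # the excess part of op k plus everything after it
    cliplen[1] <- excess
    s_total <- sum(cliplen[clipped %in% c("M", "I", "S")])
    op <- c(op[seq_len(k - 1L)], tail_op,
            if (s_total > 0L) "S")
    len <- c(len[seq_len(k - 1L)], tail_len,
             if (s_total > 0L) s_total)
  }
  # terminal insertions are unaligned read ends: soft-clip them
  if (op[1] == "I") op[1] <- "S"
  if (op[length(op)] == "I") op[length(op)] <- "S"
  # terminal deletions consume no read: fold into the offset
  off0 <- 0L
  if (op[1] == "D") { off0 <- len[1]; op <- op[-1]; len <- len[-1] }
  if (op[length(op)] == "D") {
    op <- op[-length(op)]; len <- len[-length(len)]
  }
  # a deletion stranded against a terminal soft clip is meaningless
  k <- length(op)
  if (k > 1L && op[k] == "S" && op[k - 1L] == "D") {
    op <- op[-(k - 1L)]; len <- len[-(k - 1L)]
  }
  if (strand == "+") {
    la <- leftAlignOps(op, len, qseq, substr(wseq, off0 + 1L, m))
    list(op = la$op, len = la$len, ref_offset = off0, score = ed$score)
  } else {
    # un-reverse: ops flip; offset counted from window end; the true
    # window is the first m frame characters (the rest is adapter)
    op <- rev(op); len <- rev(len)
    ref_used <- sum(len[op %in% c("M", "D")])
    off <- m - off0 - ref_used
    qf <- revStr(qseq)
    refwin <- revStr(substr(wseq, 1L, m))
    la <- leftAlignOps(op, len, qf, substr(refwin, off + 1L, m))
    list(op = la$op, len = la$len, ref_offset = off, score = ed$score)
  }
}

#' Soft-clip primer bases, reconstructing alignment coordinates
#'
#' Converts every read base whose reference placement falls inside the
#' read's own amplicon primer footprints into soft clips at the read
#' ends, advancing the alignment start past any newly clipped prefix.
#' Deletions inside a footprint are dropped from the operation list;
#' insertions anchored exactly at a primer/insert boundary are retained
#' with the insert. Sequence and qualities are untouched; the operation is
#' idempotent. Reads left with no aligned base are flagged
#' \code{fully_clipped}.
#'
#' @param aligned an \linkS4class{AlignedReads} from [alignReads()].
#' @param design a \linkS4class{PanelDesign}.
#' @return a trimmed \linkS4class{AlignedReads}.
#' @export
trimPrimers <- function(aligned, design) {
  stopifnot(is(aligned, "AlignedReads"))
  df <- readRecords(aligned)
  if (!nrow(df))
    return(new("AlignedReads", reads = df, trimmed = TRUE))
  amp <- amplicons(design)
  ai <- match(df$amplicon, mcols(amp)$id)
  if (anyNA(ai)) stop("aligned reads reference unknown amplicons")
  fwd_end <- start(amp)[ai] + mcols(amp)$fwd_len[ai] - 1L
  rev_start <- end(amp)[ai] - mcols(amp)$rev_len[ai] + 1L
  parsed <- cigarParse(df$cigar)
  for (r in seq_len(nrow(df))) {
    tr <- trimOneRead(parsed[[r]], df$start[r], fwd_end[r], rev_start[r])
    df$cigar[r] <- tr$cigar
    df$start[r] <- tr$start
    if (tr$fully_clipped) df$status[r] <- "fully_clipped"
  }
  new("AlignedReads", reads = df, trimmed = TRUE)
}

trimOneRead <- function(p, start, fwd_end, rev_start) {
  op <- p$op; len <- p$len
  nop <- character(0); nlen <- integer(0)
  rpos <- start          # next reference position
  new_start <- NA_integer_
  for (k in seq_along(op)) {
    o <- op[k]; l <- len[k]
    if (o == "S") {
      nop <- c(nop, "S"); nlen <- c(nlen, l)
    } else if (o == "M") {
      # a run splits monotonically: fwd-primer prefix / insert middle /
      # rev-primer suffix
      a <- max(0L, min(l, fwd_end - rpos + 1L))
      cc <- max(0L, min(l - a, rpos + l - rev_start))
      mm <- l - a - cc
      if (a > 0L) { nop <- c(nop, "S"); nlen <- c(nlen, a) }
      if (mm > 0L) {
        nop <- c(nop, "M"); nlen <- c(nlen, mm)
        if (is.na(new_start)) new_start <- rpos + a
      }
      if (cc > 0L) { nop <- c(nop, "S"); nlen <- c(nlen, cc) }
      rpos <- rpos + l
    } else if (o == "D") {
      keep <- max(0L, min(rpos + l - 1L, rev_start - 1L) -
                    max(rpos, fwd_end + 1L) + 1L)
      if (keep > 0L) {
        nop <- c(nop, "D"); nlen <- c(nlen, keep)
        if (is.na(new_start)) new_start <- max(rpos, fwd_end + 1L)
      }
      rpos <- rpos + l
    } else if (o == "I") {
      anchor <- rpos - 1L   # left-flanking reference base
      clip <- anchor < fwd_end || anchor >= rev_start
      nop <- c(nop, if (clip) "S" else "I"); nlen <- c(nlen, l)
    }
  }
  # deletions stranded at the clipped edges carry no read bases: drop
  # leading/trailing D runs that survived splitting
  keep <- nlen > 0L
  nop <- nop[keep]; nlen <- nlen[keep]
  first_core <- match(TRUE, nop %in% c("M", "I"))
  last_core <- length(nop) + 1L - match(TRUE, rev(nop %in% c("M", "I")))
  if (is.na(first_core)) {
    # nothing aligned: everything becomes one soft clip
    return(list(cigar = cigarBuild("S", sum(nlen[nop != "D"])),
                start = start, fully_clipped = TRUE))
  }
  drop <- nop == "D" & (seq_along(nop) < first_core |
                        seq_along(nop) > last_core)
  nop <- nop[!drop]; nlen <- nlen[!drop]
  list(cigar = cigarBuild(nop, nlen),
       start = if (is.na(new_start)) start else max(start, new_start),
       fully_clipped = !any(nop == "M"))
}
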