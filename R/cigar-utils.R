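# CIGAR helpers shared by alignment, trimming and pileup. Only the ops
# M, I, D, S are ever produced or accepted.

cigarParse <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))
  mapply(function(l, o) {
    if (length(l) != length(o))
      stop("malformed CIGAR: ", cigar)
    list(op = o, len = as.integer(l))
  }, lens, ops, SIMPLIFY = FALSE)
}

cigarBuild <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return("")
  # merge adjacent runs of the same op
  r <- rle(op)
  if (any(r$lengths > 1L)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    len <- as.integer(tapply(len, grp, sum))
    op <- r$values
  }
  paste0(len, op, collapse = "")
}

cigarReadLength <- function(cigar) {
  vapply(cigarParse(cigar), function(p)
    sum(p$len[p$op %in% c("M", "I", "S")]), integer(1))
}

cigarRefLength <- function(cigar) {
  vapply(cigarParse(cigar), function(p)
    sum(p$len[p$op %in% c("M", "D")]), integer(1))
}

# Shift every insertion/deletion to its left-most equivalent placement
# (repeat-aware, as in standard indel normalization). `refwin` is the
# reference sequence starting at `aln_start`; returns possibly updated
# op/len vectors.
leftAlignOps <- function(op, len, seq, refwin) {
  repeat {
    moved <- FALSE
    qpos <- 0L; rpos <- 0L  # consumed read / ref bases
    i <- 1L
    while (i <= length(op)) {
      o <- op[i]; l <- len[i]
      if (o %in% c("I", "D") && i > 1L && op[i - 1L] == "M" &&
          len[i - 1L] >= 1L) {
        gapseq <- if (o == "I")
          substr(seq, qpos + 1L, qpos + l)
        else
          substr(refwin, rpos + 1L, rpos + l)
        prev <- if (o == "I")
          substr(seq, qpos, qpos)
        else
          substr(refwin, rpos, rpos)
        last <- substr(gapseq, l, l)
        if (nzchar(prev) && prev == last) {
          len[i - 1L] <- len[i - 1L] - 1L
          if (i == length(op) || op[i + 1L] != "M") {
            op <- append(op, "M", after = i)
            len <- append(len, 1L, after = i)
          } else {
            len[i + 1L] <- len[i + 1L] + 1L
          }
          if (o == "I") qpos <- qpos - 1L else rpos <- rpos - 1L
          moved <- TRUE
          if (len[i - 1L] == 0L) {
            op <- op[-(i - 1L)]; len <- len[-(i - 1L)]
            i <- i - 1L
          }
          next
        }
      }
      if (o %in% c("M", "S", "I")) qpos <- qpos + l
      if (o %in% c("M", "D")) rpos <- rpos + l
      i <- i + 1L
    }
    if (!moved) break
  }
  keep <- len > 0L
  list(op = op[keep], len = len[keep])
}
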