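# Synthetic mini-genome and tiled panel generation. These stand in for the
# real six-gene loci: one contig per gene, exons separated by introns, and
# a redundant two-pass amplicon tiling over each exon plus its design
# flank. All generators are deterministic for a fixed seed.

FWD_TAIL <- "CGCTCTTCCGATCTCTG"
REV_TAIL <- "TGCTCTTCCGATCTGAC"

# single global seed fans out to per-stage child seeds so that stages can
# be re-run independently without replaying the whole stream
childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer draw on [lo, hi], safe when lo == hi
sampleRange <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

#' Generate a synthetic reference with annotated exons
#'
#' Builds one contig per gene: a leading intronic flank, then exons
#' separated by random introns, then a trailing flank. Exon coordinates
#' are recorded as the ground-truth target list.
#'
#' @param seed integer seed; output is bit-reproducible for a fixed seed.
#' @param nGenes number of genes (one contig each).
#' @param exonsPerGene integer vector (recycled to \code{nGenes}).
#' @param exonLenRange,intronLenRange length-2 ranges sampled uniformly.
#' @param exonLens optional explicit exon lengths (vector over all exons in
#'   order), overriding \code{exonLenRange}.
#' @param flankLen intronic sequence before the first / after the last exon.
#' @param codingFraction fraction of exons marked coding (the rest are
#'   non-coding and excluded from the reportable range); the first exons of
#'   each gene stay coding.
#' @return list with \code{reference} (\code{DNAStringSet}) and
#'   \code{targets} (\code{GRanges} with gene/exon/coding columns).
#' @export
makeReference <- function(seed = 1L, nGenes = 6L,
                          exonsPerGene = c(16L, 16L, 15L, 15L, 15L, 15L),
                          exonLenRange = c(120L, 360L),
                          intronLenRange = c(600L, 3200L),
                          exonLens = NULL, flankLen = 400L,
                          codingFraction = 1) {
  stopifnot(nGenes >= 1, flankLen >= 0,
            all(exonLenRange > 0), all(intronLenRange > 0))
  set.seed(childSeed(seed, 1L))
  exonsPerGene <- rep_len(as.integer(exonsPerGene), nGenes)
  total <- sum(exonsPerGene)
  lens <- if (is.null(exonLens)) {
    sampleRange(exonLenRange[1], exonLenRange[2], total)
  } else {
    stopifnot(length(exonLens) == total)
    as.integer(exonLens)
  }
  seqs <- character(nGenes)
  rows <- vector("list", nGenes)
  k <- 0L
  for (g in seq_len(nGenes)) {
    ctg <- paste0("ctg", g)
    pos <- flankLen
    parts <- list(randomDna(flankLen))
    st <- en <- integer(exonsPerGene[g])
    for (e in seq_len(exonsPerGene[g])) {
      k <- k + 1L
      st[e] <- pos + 1L
      en[e] <- pos + lens[k]
      parts <- c(parts, randomDna(lens[k]))
      pos <- en[e]
      if (e < exonsPerGene[g]) {
        il <- sampleRange(intronLenRange[1], intronLenRange[2])
        parts <- c(parts, randomDna(il))
        pos <- pos + il
      }
    }
    parts <- c(parts, randomDna(flankLen))
    seqs[g] <- paste(unlist(parts), collapse = "")
    rows[[g]] <- data.frame(contig = ctg, start = st, end = en,
                            gene = paste0("G", g),
                            exon = seq_len(exonsPerGene[g]),
                            stringsAsFactors = FALSE)
  }
  names(seqs) <- paste0("ctg", seq_len(nGenes))
  tab <- do.call(rbind, rows)
  coding <- rep(TRUE, nrow(tab))
  if (codingFraction < 1) {
    n_nc <- round((1 - codingFraction) * nrow(tab))
    if (n_nc > 0) {
      idx <- which(tab$exon > 1L)
      coding[sample(idx, min(n_nc, length(idx)))] <- FALSE
    }
  }
  gr <- GRanges(tab$contig, IRanges(tab$start, tab$end))
  mcols(gr) <- DataFrame(gene = tab$gene, exon = tab$exon, coding = coding)
  list(reference = DNAStringSet(seqs), targets = gr)
}

#' Generate a redundant tiled amplicon design
#'
#' Tiles each coding exon plus \code{designFlank} intronic bases with
#' \code{passes} staggered passes of amplicons so that interior target
#' bases fall in at least two inserts where the geometry allows; adapter
#' tails are attached verbatim. Primer sequences are copied from the
#' reference at their footprints (reverse primer as reverse complement).
#'
#' @param reference \code{DNAStringSet}.
#' @param targetExons \code{GRanges} from [makeReference()].
#' @param ampliconLenRange sampled amplicon outer lengths (default 110-199).
#' @param primerLen primer footprint length in bases.
#' @param tileOverlap insert overlap (bp) between consecutive amplicons of
#'   one pass.
#' @param passes number of staggered tiling passes (2 gives the redundant
#'   design; 1 gives a deliberately drop-out-prone panel).
#' @param designFlank intronic flank tiled around each exon (the design
#'   flank, distinct from the 5-bp reporting flank).
#' @param flank reporting flank forwarded to [panelDesign()].
#' @param seed integer seed.
#' @return a validated \linkS4class{PanelDesign}.
#' @export
makeDesign <- function(reference, targetExons,
                       ampliconLenRange = c(110L, 199L), primerLen = 18L,
                       tileOverlap = 10L, passes = 2L, designFlank = 50L,
                       flank = 5L, seed = 1L) {
  stopifnot(ampliconLenRange[1] > 2 * primerLen)
  set.seed(childSeed(seed, 2L))
  coding <- targetExons[mcols(targetExons)$coding]
  rows <- list()
  for (i in seq_along(coding)) {
    ctg <- as.character(seqnames(coding))[i]
    clen <- Biostrings::width(reference)[names(reference) == ctg]
    rstart <- start(coding)[i] - designFlank
    rend <- end(coding)[i] + designFlank
    if (rstart - primerLen < 1L || rend + primerLen > clen)
      stop("amplicon tiling infeasible for exon ",
           mcols(coding)$gene[i], ":", mcols(coding)$exon[i],
           " (insufficient contig flank)")
    lab <- paste0(mcols(coding)$gene[i], "e", mcols(coding)$exon[i])
    for (p in seq_len(passes)) {
      L <- sampleRange(ampliconLenRange[1], ampliconLenRange[2])
      insLen <- L - 2L * primerLen
      cur <- rstart + (p - 1L) * insLen %/% passes
      if (p > 1L) cur <- max(rstart, cur - insLen %/% (2L * passes))
      j <- 0L
      while (cur <= rend) {
        j <- j + 1L
        L <- sampleRange(ampliconLenRange[1], ampliconLenRange[2])
        insLen <- L - 2L * primerLen
        ins_start <- cur
        ins_end <- min(ins_start + insLen - 1L, clen - primerLen)
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(lab, letters[p], j), contig = ctg,
          outer_start = ins_start - primerLen,
          outer_end = ins_end + primerLen, stringsAsFactors = FALSE)
        cur <- ins_end - tileOverlap + 1L
        if (ins_end >= rend) break
      }
    }
  }
  tab <- do.call(rbind, rows)
  # amplicons sharing an outer start (or end) would share a primer and
  # make read assignment ambiguous; keep the longer of any such pair
  # (its span contains everything the shorter one covered)
  tab <- tab[order(tab$outer_end - tab$outer_start, decreasing = TRUE), ]
  keep <- !duplicated(paste(tab$contig, tab$outer_start)) &
          !duplicated(paste(tab$contig, tab$outer_end))
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$contig, tab$outer_start, tab$outer_end), ,
             drop = FALSE]
  amp <- GRanges(tab$contig, IRanges(tab$outer_start, tab$outer_end))
  fwd_seq <- rev_seq <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    s <- reference[[tab$contig[r]]]
    fwd_seq[r] <- as.character(subseq(s, tab$outer_start[r],
                                      tab$outer_start[r] + primerLen - 1L))
    rev_seq[r] <- as.character(reverseComplement(
      subseq(s, tab$outer_end[r] - primerLen + 1L, tab$outer_end[r])))
  }
  mcols(amp) <- DataFrame(id = tab$id, fwd_len = primerLen,
                          rev_len = primerLen, fwd_seq = fwd_seq,
                          rev_seq = rev_seq, fwd_tail = FWD_TAIL,
                          rev_tail = REV_TAIL)
  design <- panelDesign(amp, targetExons, reference, flank = flank,
                        lenBounds = ampliconLenRange)
  validatePanelDesign(design)
  design
}
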