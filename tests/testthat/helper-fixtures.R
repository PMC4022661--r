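# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-derivations (brute force / enumeration) kept free of the package's
# own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

rcChr <- function(x) as.character(reverseComplement(DNAString(x)))

randomContig <- function(len, seed) {
  set.seed(seed)
  DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "ctgX"))
}

# build an amplicon GRanges row with primer sequences read off `ref`
manualAmplicon <- function(ref, ctg, start, end, id, fl = 18L, rl = 18L) {
  gr <- GRanges(ctg, IRanges(start, end))
  fwd <- as.character(subseq(ref[[ctg]], start, start + fl - 1L))
  rev <- rcChr(as.character(subseq(ref[[ctg]], end - rl + 1L, end)))
  mcols(gr) <- S4Vectors::DataFrame(
    id = id, fwd_len = fl, rev_len = rl, fwd_seq = fwd, rev_seq = rev,
    fwd_tail = "CGCTCTTCCGATCTCTG", rev_tail = "TGCTCTTCCGATCTGAC")
  gr
}

simpleExons <- function(ctg, starts, ends, gene = "G1") {
  gr <- GRanges(ctg, IRanges(starts, ends))
  mcols(gr) <- S4Vectors::DataFrame(gene = gene,
                                    exon = seq_along(starts),
                                    coding = TRUE)
  gr
}

# two overlapping amplicons where a variant sits under A's reverse primer
# footprint but inside B's insert (the primer-dilution geometry); variant
# is a 4-bp duplication-style insertion anchored at `vpos`
dilutionFixture <- function(seed = 101L, vpos = 195L) {
  ref <- randomContig(400L, seed)
  ampA <- manualAmplicon(ref, "ctgX", 51L, 200L, "ampA")
  ampB <- manualAmplicon(ref, "ctgX", 171L, 320L, "ampB")
  exons <- simpleExons("ctgX", 100L, 290L)
  design <- panelDesign(c(ampA, ampB), exons, ref, flank = 5L,
                        lenBounds = c(110L, 199L))
  anchor <- as.character(subseq(ref[["ctgX"]], vpos, vpos))
  list(design = design, ref = ref, vpos = vpos, anchor = anchor,
       alt = paste0(anchor, "CTTC"),
       key = sprintf("ctgX:%d:%s>%s%s", vpos, anchor, anchor, "CTTC"))
}

cleanQuals <- function(meanDepth = 200, depthCV = 0,
                       dropoutFactor = 0) {
  errorModel(qualLevels = 35L, qualProbs = 1, errorScale = 0,
             meanDepth = meanDepth, depthCV = depthCV,
             dropoutFactor = dropoutFactor)
}

runCallPipeline <- function(design, truth, em, depths = NULL, seed = 1L,
                            config = filterConfig(), trim = TRUE,
                            region = NULL,
                            alleleAssignment = "random") {
  sim <- simulateReads(design, truth, em = em, depths = depths,
                       seed = seed, alleleAssignment = alleleAssignment)
  asn <- assignReads(sim$reads, design)
  aln <- alignReads(sim$reads, asn, design)
  reads <- if (trim) trimPrimers(aln$aligned, design) else aln$aligned
  if (is.null(region)) region <- reportableRange(design)
  pile <- pileupReads(reads, region, config)
  list(sim = sim, asn = asn, aln = aln, reads = reads, pile = pile,
       cand = callVariants(pile, refSequence(design), config,
                           reportable = reportableRange(design)))
}

# position inside the first target exon that no primer footprint covers
# (variants there exercise calling, not the drop-out model); for
# deletion fixtures (span 2) the site is also chosen so ref[p] differs
# from ref[p+1], keeping the left-anchored truth key already canonical
footprintFreeSite <- function(design, span = 1L) {
  ex <- targets(design)[1]
  fp <- ampliDx::primerFootprints(design)
  cand <- start(ex):(end(ex) - span + 1L)
  bad <- unique(unlist(lapply(seq_along(fp), function(i)
    start(fp)[i]:end(fp)[i])))
  free <- cand[!(cand %in% bad) & !((cand + span - 1L) %in% bad)]
  if (span >= 2L) {
    ctg <- as.character(seqnames(ex))
    s <- as.character(refSequence(design)[[ctg]])
    free <- free[substring(s, free, free) !=
                 substring(s, free + 1L, free + 1L)]
    # keep the event strictly interior to every covering insert: a
    # deletion stranded against a primer clip loses its D op
    ins <- ampliDx::ampliconInserts(design)
    ok <- vapply(free, function(p) {
      ov <- start(ins) <= p + span - 1L & end(ins) >= p
      all(start(ins)[ov] + 1L <= p &
          p + span - 1L <= end(ins)[ov] - 1L)
    }, logical(1))
    free <- free[ok]
  }
  if (!length(free)) stop("no footprint-free site in the first exon")
  free[ceiling(length(free) / 2)]
}

# --- oracles -----------------------------------------------------------

# brute-force per-base interval stabbing count
oracleCoverage <- function(positions, starts, ends) {
  vapply(positions, function(p) sum(starts <= p & p <= ends), integer(1))
}

# exhaustive primer-footprint scan
oracleFootprintHits <- function(design, positions) {
  amp <- amplicons(design)
  hits <- 0L
  for (i in seq_along(amp)) {
    f1 <- start(amp)[i]; f2 <- f1 + mcols(amp)$fwd_len[i] - 1L
    r2 <- end(amp)[i]; r1 <- r2 - mcols(amp)$rev_len[i] + 1L
    hits <- hits + sum((positions >= f1 & positions <= f2) |
                       (positions >= r1 & positions <= r2))
  }
  hits
}

# exhaustive Hamming-distance read assignment (mirrors the documented
# contract, not the package's dictionary + rescue implementation)
oracleAssign <- function(seq, design, maxMismatch = 2L) {
  amp <- amplicons(design)
  best <- Inf; bid <- NA_character_
  for (i in seq_along(amp)) {
    for (cand in list(
      c(mcols(amp)$fwd_seq[i], mcols(amp)$id[i]),
      c(paste0(mcols(amp)$fwd_tail[i], mcols(amp)$fwd_seq[i]),
        mcols(amp)$id[i]),
      c(mcols(amp)$rev_seq[i], mcols(amp)$id[i]),
      c(paste0(mcols(amp)$rev_tail[i], mcols(amp)$rev_seq[i]),
        mcols(amp)$id[i]))) {
      L <- nchar(cand[1])
      if (nchar(seq) < L) next
      mm <- sum(utf8ToInt(substr(seq, 1, L)) != utf8ToInt(cand[1]))
      if (mm <= maxMismatch &&
          (mm < best || (mm == best && !is.na(bid) && cand[2] < bid)))
        { best <- mm; bid <- cand[2] }
    }
  }
  bid
}

# naive pileup tally straight off the alignment records
oraclePileup <- function(alnDf, winStart, winEnd, minQual = 20L) {
  L <- winEnd - winStart + 1L
  cnt <- matrix(0L, nrow = L, ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "DEL")))
  for (r in seq_len(nrow(alnDf))) {
    ops <- regmatches(alnDf$cigar[r], gregexpr("[0-9]+[MIDS]",
                                               alnDf$cigar[r]))[[1]]
    rpos <- alnDf$start[r]; qpos <- 0L
    for (o in ops) {
      l <- as.integer(substr(o, 1, nchar(o) - 1))
      t <- substr(o, nchar(o), nchar(o))
      if (t == "M") {
        for (k in seq_len(l)) {
          p <- rpos + k - 1L
          if (p >= winStart && p <= winEnd) {
            q <- utf8ToInt(substr(alnDf$qual[r], qpos + k, qpos + k)) - 33L
            if (q >= minQual) {
              b <- substr(alnDf$seq[r], qpos + k, qpos + k)
              if (b %in% colnames(cnt))
                cnt[p - winStart + 1L, b] <- cnt[p - winStart + 1L, b] + 1L
            }
          }
        }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (t == "D") {
        for (k in seq_len(l)) {
          p <- rpos + k - 1L
          if (p >= winStart && p <= winEnd)
            cnt[p - winStart + 1L, "DEL"] <-
              cnt[p - winStart + 1L, "DEL"] + 1L
        }
        rpos <- rpos + l
      } else if (t %in% c("I", "S")) {
        qpos <- qpos + l
      }
    }
  }
  cnt
}

# exhaustive all-intervals greedy segmentation: repeatedly accept the
# best-scoring interval (|mean| * sqrt(n) / sd) not overlapping an
# accepted one, then merge adjacent same-sign neighbours
oracleSegment <- function(x, sd, thresh = 6) {
  n <- length(x)
  sc <- matrix(-Inf, n, n)
  mu <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    m <- mean(x[i:j])
    mu[i, j] <- m
    sc[i, j] <- abs(m) * sqrt(j - i + 1) / sd
  }
  taken <- list(); blocked <- matrix(FALSE, n, n)
  repeat {
    sc2 <- sc; sc2[blocked] <- -Inf
    k <- which.max(sc2)
    if (sc2[k] < thresh) break
    i <- (k - 1) %% n + 1; j <- (k - 1) %/% n + 1
    taken[[length(taken) + 1]] <- c(i, j)
    for (a in 1:n) for (b in a:n)
      if (!(b < i || a > j)) blocked[a, b] <- TRUE
  }
  if (!length(taken)) return(data.frame(from = integer(),
                                        to = integer()))
  m <- do.call(rbind, taken)
  m <- m[order(m[, 1]), , drop = FALSE]
  i <- 1
  while (i < nrow(m)) {
    if (m[i, 2] + 1 == m[i + 1, 1] &&
        sign(mean(x[m[i, 1]:m[i, 2]])) ==
          sign(mean(x[m[i + 1, 1]:m[i + 1, 2]]))) {
      m[i, 2] <- m[i + 1, 2]
      m <- m[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  data.frame(from = m[, 1], to = m[, 2])
}
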