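# Read assignment, primer-anchored alignment, soft-clip trimming and the
# on-target metric.

test_that("assignment honours the mismatch threshold and matches brute force", {
  g <- makeReference(seed = 51, nGenes = 1, exonsPerGene = 2)
  d <- makeDesign(g$reference, g$targets, seed = 51)
  amp <- amplicons(d)
  primer <- mcols(amp)$fwd_seq[1]
  rest <- paste(rep("A", 100), collapse = "")
  mk <- function(s) data.frame(read_id = "r", seq = paste0(s, rest),
                               qual = strrep("I", nchar(s) + 100),
                               stringsAsFactors = FALSE)
  # exact prefix
  expect_equal(assignReads(mk(primer), d)$amplicon, mcols(amp)$id[1])
  # 1 mismatch within threshold 2, 3 mismatches over it
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  expect_equal(assignReads(mk(mut(primer, 1)), d, maxMismatch = 2)$amplicon,
               mcols(amp)$id[1])
  expect_true(is.na(assignReads(mk(mut(primer, 3)), d,
                                maxMismatch = 2)$amplicon))
  # adapter-tailed prefix is recognized and clipped
  tailed <- mk(paste0(mcols(amp)$fwd_tail[1], primer))
  got <- assignReads(tailed, d)
  expect_equal(got$amplicon, mcols(amp)$id[1])
  expect_equal(got$clip5, nchar(mcols(amp)$fwd_tail[1]))
  # random reads: dictionary + rescue equals the exhaustive Hamming scan
  sim <- simulateReads(d, sampleTruth(), em = errorModel(meanDepth = 30),
                       seed = 53, decoyFraction = 0.2)
  got <- assignReads(sim$reads, d)
  want <- vapply(sim$reads$seq, oracleAssign, character(1), design = d)
  expect_identical(unname(got$amplicon), unname(want))
})

test_that("on-target rate reflects decoy load", {
  g <- makeReference(seed = 55, nGenes = 1, exonsPerGene = 1)
  d <- makeDesign(g$reference, g$targets, seed = 55)
  sim <- simulateReads(d, sampleTruth(), em = cleanQuals(meanDepth = 250),
                       seed = 57, decoyFraction = 0.1)
  asn <- assignReads(sim$reads, d)
  expect_equal(onTargetRate(asn), 0.9, tolerance = 0.02)
  all_on <- assignReads(sim$reads[!is.na(sim$reads$amplicon), ], d)
  expect_equal(onTargetRate(all_on), 1.0)
  half <- data.frame(read_id = c("a", "b"),
                     amplicon = c("x", NA), stringsAsFactors = FALSE)
  expect_equal(onTargetRate(half), 0.5)
})

test_that("error-free reads align as a single M run at the primer anchor", {
  g <- makeReference(seed = 59, nGenes = 1, exonsPerGene = 1)
  d <- makeDesign(g$reference, g$targets, seed = 59)
  sim <- simulateReads(d, sampleTruth(), em = cleanQuals(meanDepth = 30),
                       seed = 61)
  asn <- assignReads(sim$reads, d)
  aln <- alignReads(sim$reads, asn, d)
  df <- readRecords(aln$aligned)
  expect_equal(nrow(aln$rejects), 0L)
  # no indels; a single M run, plus a soft clip only where the read ran
  # past the amplicon into the adapter tail
  expect_true(all(grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", df$cigar)))
  amp <- amplicons(d)
  i <- match(df$amplicon, mcols(amp)$id)
  fwd <- df$strand == "+"
  expect_true(all(df$start[fwd] == start(amp)[i][fwd]))
  reflen <- vapply(regmatches(df$cigar, gregexpr("[0-9]+(?=M)",
                                                 df$cigar, perl = TRUE)),
                   function(x) sum(as.integer(x)), numeric(1))
  ends <- df$start + reflen - 1L
  expect_true(all(ends[!fwd] == end(amp)[i][!fwd]))
  # reads fitting inside their amplicon are one clean M spanning the read
  fits <- nchar(df$seq) <= width(amp)[i]
  expect_true(all(grepl("^[0-9]+M$", df$cigar[fits & fwd])))
})

test_that("mid-insert insertions are reported left-aligned", {
  fx <- dilutionFixture()
  truth <- sampleTruth(variants = data.frame(
    contig = "ctgX", pos = fx$vpos, ref = fx$anchor, alt = fx$alt,
    zygosity = "hom", stringsAsFactors = FALSE))
  sim <- simulateReads(fx$design, truth,
                       em = cleanQuals(dropoutFactor = 1),
                       depths = c(ampA = 0L, ampB = 30L), seed = 63)
  asn <- assignReads(sim$reads, fx$design)
  aln <- alignReads(sim$reads, asn, fx$design)
  df <- readRecords(aln$aligned)
  with_i <- grepl("I", df$cigar)
  expect_true(all(with_i))
  # independent left-most position: slide the 4-mer left over the
  # reference while the base before the gap equals the gap's last base
  refseq <- as.character(fx$ref[["ctgX"]])
  insseq <- "CTTC"; anchor <- fx$vpos
  while (substr(refseq, anchor, anchor) ==
         substr(insseq, nchar(insseq), nchar(insseq))) {
    insseq <- paste0(substr(refseq, anchor, anchor),
                     substr(insseq, 1, nchar(insseq) - 1))
    anchor <- anchor - 1L
  }
  for (r in which(df$strand == "+")) {
    p <- cumsum(c(df$start[r] - 1L,
                  as.integer(regmatches(df$cigar[r],
                    gregexpr("[0-9]+", df$cigar[r]))[[1]])))
    ops <- regmatches(df$cigar[r], gregexpr("[MIDS]", df$cigar[r]))[[1]]
    # reference position just before the I op
    lens <- as.integer(regmatches(df$cigar[r],
                                  gregexpr("[0-9]+", df$cigar[r]))[[1]])
    rpos <- df$start[r]
    for (k in seq_along(ops)) {
      if (ops[k] == "I") break
      if (ops[k] %in% c("M", "D")) rpos <- rpos + lens[k]
    }
    expect_equal(rpos - 1L, anchor)
  }
  # alignment scores agree with an independent global-local aligner
  core <- sim$reads$seq[sim$reads$strand == "+"][1]
  win <- as.character(subseq(fx$ref[["ctgX"]], 171L, 320L))
  pa <- Biostrings::pairwiseAlignment(
    core, win, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 3, gapExtension = 1)
  ours <- ampliDx:::alignAnchored(core, win, "+", 12L,
                                  list(match = 1, mismatch = -1,
                                       gapOpen = -3, gapExt = -1,
                                       minFrac = 0.4))
  expect_equal(ours$score, Biostrings::score(pa))
})

test_that("banded aligner reproduces Needleman-Wunsch on small cases", {
  set.seed(7)
  sp <- list(match = 1, mismatch = -1, gapOpen = -3, gapExt = -1,
             minFrac = 0.1)
  for (i in 1:20) {
    ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    # mutate: substitutions and one indel
    v <- strsplit(ref, "")[[1]]
    j <- sample(10:40, 1)
    read <- if (i %% 2 == 0)
      paste(c(v[1:j], sample(c("A", "C", "G", "T"), 3, TRUE),
              v[(j + 1):50]), collapse = "")
    else paste(v[c(1:j, (j + 4):50)], collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      read, ref, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 3, gapExtension = 1)
    ours <- ampliDx:::alignAnchored(read, ref, "+", 12L, sp)
    expect_equal(ours$score, Biostrings::score(pa))
    # read length is conserved by the op list
    expect_equal(sum(ours$len[ours$op %in% c("M", "I", "S")]),
                 nchar(read))
  }
})

test_that("primer trimming soft-clips footprints and reconstructs starts", {
  fx <- dilutionFixture()
  sim <- simulateReads(fx$design, sampleTruth(), em = cleanQuals(),
                       depths = c(ampA = 20L, ampB = 20L), seed = 65)
  asn <- assignReads(sim$reads, fx$design)
  aln <- alignReads(sim$reads, asn, fx$design)
  trm <- trimPrimers(aln$aligned, fx$design)
  df0 <- readRecords(aln$aligned)
  df1 <- readRecords(trm)
  # 150 bp read, 18 bp fwd primer: leading 18 bases clipped, start += 18
  fwdA <- df1$amplicon == "ampA" & df1$strand == "+"
  expect_true(all(grepl("^18S114M18S$", df1$cigar[fwdA])))
  expect_true(all(df1$start[fwdA] == df0$start[fwdA] + 18L))
  # read count, sequence and length conserved
  expect_equal(nrow(df1), nrow(df0))
  expect_identical(df1$seq, df0$seq)
  expect_identical(df1$qual, df0$qual)
  # idempotence
  trm2 <- trimPrimers(trm, fx$design)
  expect_identical(readRecords(trm2), readRecords(trm))
  # no M op overlaps a footprint afterwards
  amp <- amplicons(fx$design)
  fp <- ampliDx::primerFootprints(fx$design)
  pile <- pileupReads(trm, GRanges("ctgX", IRanges(51L, 320L)),
                      filterConfig(minBaseQual = 0))
  cc <- pile$columns
  # under ampA's own rev primer [183,200]: only ampB insert depth remains
  expect_true(all(cc$depth[cc$pos >= 189 & cc$pos <= 200] == 20L))
  # in ampA's fwd primer [51,68], no other amplicon reaches: depth 0
  expect_true(all(cc$depth[cc$pos >= 51 & cc$pos <= 68] == 0L))
})

test_that("reads entirely within primer footprints are flagged unusable", {
  fx <- dilutionFixture()
  # a fake alignment sitting wholly inside ampA's forward primer
  df <- data.frame(read_id = "stub", amplicon = "ampA", contig = "ctgX",
                   start = 53L, cigar = "10M", seq = strrep("A", 10),
                   qual = strrep("I", 10), strand = "+",
                   status = "aligned", stringsAsFactors = FALSE)
  ar <- new("AlignedReads", reads = df, trimmed = FALSE)
  trm <- trimPrimers(ar, fx$design)
  out <- readRecords(trm)
  expect_equal(out$status, "fully_clipped")
  expect_equal(out$cigar, "10S")
})

test_that("SAM output round-trips through Rsamtools", {
  skip_if_not_installed("Rsamtools")
  g <- makeReference(seed = 67, nGenes = 1, exonsPerGene = 1)
  d <- makeDesign(g$reference, g$targets, seed = 67)
  sim <- simulateReads(d, sampleTruth(), em = cleanQuals(meanDepth = 15),
                       seed = 69)
  asn <- assignReads(sim$reads, d)
  aln <- alignReads(sim$reads, asn, d)
  trm <- trimPrimers(aln$aligned, d)
  sam <- tempfile(fileext = ".sam")
  writeSam(trm, refSequence(d), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  df <- readRecords(trm)
  ord <- order(df$read_id)
  got <- order(as.character(rec$qname))
  expect_equal(as.character(rec$qname)[got], df$read_id[ord])
  expect_equal(rec$pos[got], df$start[ord])
  expect_equal(as.character(rec$cigar)[got], df$cigar[ord])
})
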