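# Pileup correctness against a naive tally, the clinical filter chain,
# low-coverage flagging and the confirmation worklist.

test_that("pileup counts equal a naive per-base tally", {
  g <- makeReference(seed = 71, nGenes = 1, exonsPerGene = 1)
  d <- makeDesign(g$reference, g$targets, seed = 71)
  sim <- simulateReads(d, sampleTruth(), em = errorModel(meanDepth = 25),
                       seed = 73)
  asn <- assignReads(sim$reads, d)
  aln <- alignReads(sim$reads, asn, d)
  trm <- trimPrimers(aln$aligned, d)
  rr <- reportableRange(d)
  pile <- pileupReads(trm, rr)
  cc <- pile$columns
  want <- oraclePileup(readRecords(trm), start(rr)[1], end(rr)[1])
  sel <- cc$contig == as.character(seqnames(rr))[1] &
    cc$pos >= start(rr)[1] & cc$pos <= end(rr)[1]
  for (a in c("A", "C", "G", "T", "DEL"))
    expect_identical(unname(cc[[a]][sel]), unname(want[, a]))
  # depth conservation: allele counts sum to depth
  expect_equal(cc$depth, cc$A + cc$C + cc$G + cc$T + cc$N + cc$DEL)
  # 100 error-free reference reads give depth 100, ref count 100
  fx <- dilutionFixture()
  sim2 <- simulateReads(fx$design, sampleTruth(), em = cleanQuals(),
                        depths = c(ampA = 100L, ampB = 0L), seed = 75)
  asn2 <- assignReads(sim2$reads, fx$design)
  aln2 <- alignReads(sim2$reads, asn2, fx$design)
  pile2 <- pileupReads(aln2$aligned, GRanges("ctgX", IRanges(100L, 120L)),
                       filterConfig())
  cc2 <- pile2$columns
  expect_true(all(cc2$depth == 100L))
  for (p in cc2$pos) {
    b <- as.character(subseq(fx$ref[["ctgX"]], p, p))
    expect_equal(cc2[[b]][cc2$pos == p], 100L)
  }
})

test_that("base-quality floor excludes low-quality bases from counts", {
  fx <- dilutionFixture()
  em <- errorModel(qualLevels = c(10L, 35L), qualProbs = c(0.3, 0.7),
                   errorScale = 0, meanDepth = 200, depthCV = 0)
  sim <- simulateReads(fx$design, sampleTruth(), em = em,
                       depths = c(ampA = 200L, ampB = 0L), seed = 77)
  asn <- assignReads(sim$reads, fx$design)
  aln <- alignReads(sim$reads, asn, fx$design)
  region <- GRanges("ctgX", IRanges(100L, 140L))
  strict <- pileupReads(aln$aligned, region,
                        filterConfig(minBaseQual = 20L))
  loose <- pileupReads(aln$aligned, region,
                       filterConfig(minBaseQual = 0L))
  expect_true(all(loose$columns$depth == 200L))
  expect_true(all(strict$columns$depth < 200L))
  expect_equal(mean(strict$columns$depth) / 200, 0.7, tolerance = 0.05)
})

test_that("allele-count threshold gates emission except for protected variants", {
  # synthetic pileup via constructed aligned reads: 49 alt vs 51 alt
  ref <- randomContig(300L, seed = 81)
  refseq <- as.character(ref[["ctgX"]])
  mkreads <- function(nalt, pos, alt, depth = 100L) {
    wt <- substr(refseq, 51L, 200L)
    mt <- wt
    substr(mt, pos - 50L, pos - 50L) <- alt
    data.frame(
      read_id = sprintf("r%03d", seq_len(depth)),
      amplicon = "ampA", contig = "ctgX", start = 51L, cigar = "150M",
      seq = c(rep(mt, nalt), rep(wt, depth - nalt)),
      qual = strrep("I", 150L), strand = "+", status = "aligned",
      stringsAsFactors = FALSE)
  }
  pos <- 120L
  refb <- substr(refseq, 120L, 120L)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  region <- GRanges("ctgX", IRanges(100L, 140L))
  key <- sprintf("ctgX:%d:%s>%s", pos, refb, altb)
  for (nalt in c(49L, 50L)) {
    ar <- new("AlignedReads", reads = mkreads(nalt, pos, altb),
              trimmed = TRUE)
    pile <- pileupReads(ar, region)
    cand <- callVariants(pile, ref, filterConfig())
    if (nalt < 50L) expect_equal(nrow(cand), 0L)
    else {
      expect_equal(nrow(cand), 1L)
      expect_equal(cand$alt_count, 50L)
      expect_equal(cand$allele_ratio, 0.5)
    }
  }
  # protection rescues a below-threshold known causative variant
  ar <- new("AlignedReads", reads = mkreads(30L, pos, altb),
            trimmed = TRUE)
  pile <- pileupReads(ar, region)
  cand <- callVariants(pile, ref,
                       filterConfig(protectedVariants = key))
  expect_equal(nrow(cand), 1L)
  expect_true(cand$protected)
  expect_match(cand$filters, "LowAlleleCount")
  # raising the floor never adds calls (monotonicity)
  ar2 <- new("AlignedReads", reads = mkreads(60L, pos, altb),
             trimmed = TRUE)
  pile2 <- pileupReads(ar2, region)
  n_at <- vapply(c(10L, 50L, 61L), function(thr)
    nrow(callVariants(pile2, ref, filterConfig(minAltReads = thr))),
    integer(1))
  expect_true(all(diff(n_at) <= 0))
  # low-ratio calls are tiered for review, not dropped
  ar3 <- new("AlignedReads",
             reads = mkreads(60L, pos, altb, depth = 400L),
             trimmed = TRUE)
  cand3 <- callVariants(pileupReads(ar3, region), ref, filterConfig())
  expect_equal(cand3$risk_tier, "low_ratio_review")
  expect_equal(cand3$allele_ratio, 0.15)
})

test_that("low-coverage intervals are maximal, merged and boundary-inclusive", {
  ref <- randomContig(300L, seed = 83)
  mk <- function(depths, startpos = 101L) {
    # one fake read per unit of depth, each 1 bp long
    rows <- list()
    for (i in seq_along(depths)) {
      dd <- depths[i]
      if (dd > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("p%d_%d", i, seq_len(dd)),
          amplicon = "a", contig = "ctgX",
          start = startpos + i - 1L, cigar = "1M",
          seq = substr(as.character(ref[["ctgX"]]), startpos + i - 1L,
                       startpos + i - 1L),
          qual = "I", strand = "+", status = "aligned",
          stringsAsFactors = FALSE)
    }
    new("AlignedReads",
        reads = do.call(rbind, c(rows, list(make.row.names = FALSE))),
        trimmed = TRUE)
  }
  depths <- c(60L, 50L, 49L, 60L, 0L, 51L, 50L, 60L)
  pile <- pileupReads(mk(depths), GRanges("ctgX", IRanges(101L, 108L)))
  low <- flagLowCoverage(pile, filterConfig())
  # brute-force scan oracle
  flagged <- which(depths <= 50L)
  runs <- split(flagged, cumsum(c(1, diff(flagged) != 1)))
  expect_equal(length(low), length(runs))
  expect_equal(start(low), 100L + vapply(runs, min, numeric(1),
                                         USE.NAMES = FALSE))
  expect_equal(end(low), 100L + vapply(runs, max, numeric(1),
                                       USE.NAMES = FALSE))
  # a single base at exactly the threshold is flagged (inclusive <=)
  one <- pileupReads(mk(c(60L, 50L, 60L)),
                     GRanges("ctgX", IRanges(101L, 103L)))
  lone <- flagLowCoverage(one, filterConfig())
  expect_equal(length(lone), 1L)
  expect_equal(start(lone), 102L)
  expect_equal(end(lone), 102L)
  # uniform deep coverage flags nothing
  deep <- pileupReads(mk(rep(60L, 8L)),
                      GRanges("ctgX", IRanges(101L, 108L)))
  expect_equal(length(flagLowCoverage(deep, filterConfig())), 0L)
})

test_that("common polymorphisms are filtered unless protected", {
  cand <- data.frame(
    contig = "c1", pos = c(10L, 20L, 30L, 40L), ref = "A",
    alt = c("T", "G", "C", "T"), depth = 100L, alt_count = 60L,
    mean_alt_qual = 35, allele_ratio = 0.6,
    key = c("c1:10:A>T", "c1:20:A>G", "c1:30:A>C", "c1:40:A>T"),
    protected = c(FALSE, FALSE, TRUE, FALSE),
    risk_tier = "standard", filters = c("", "", "", "OffReportable"),
    stringsAsFactors = FALSE)
  freq <- c("c1:10:A>T" = 0.30, "c1:30:A>C" = 0.30)
  out <- filterPolymorphisms(cand, freq, filterConfig())
  # set-algebra oracle: reportable = not (common & unprotected) minus
  # off-reportable unprotected
  expect_equal(out$reportable, c(FALSE, TRUE, TRUE, FALSE))
  expect_match(out$filters[1], "CommonPolymorphism")
  expect_false(grepl("CommonPolymorphism", out$filters[3]))
  # frequency below the cutoff is kept
  out2 <- filterPolymorphisms(cand[2, ], c("c1:20:A>G" = 0.001),
                              filterConfig())
  expect_true(out2$reportable)
})

test_that("confirmation worklist unions variants and low-cov regions, deduped", {
  rep_df <- data.frame(
    contig = "c1", pos = c(10L, 10L, 25L), ref = c("A", "A", "G"),
    alt = c("T", "T", "C"), key = c("c1:10:A>T", "c1:10:A>T",
                                    "c1:25:G>C"),
    reportable = TRUE, stringsAsFactors = FALSE)
  low <- GRanges("c1", IRanges(c(100L), c(120L)))
  wl <- confirmationWorklist(rep_df, low)
  expect_equal(nrow(wl), 3L)
  expect_equal(sum(wl$type == "variant"), 2L)
  expect_equal(sum(wl$type == "low_coverage"), 1L)
  expect_true(!is.unsorted(wl$start))
  empty <- confirmationWorklist(rep_df[0, ], GRanges())
  expect_equal(nrow(empty), 0L)
})

test_that("VCF output round-trips through VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  fx <- dilutionFixture()
  truth <- sampleTruth(variants = data.frame(
    contig = "ctgX", pos = fx$vpos, ref = fx$anchor, alt = fx$alt,
    zygosity = "het", stringsAsFactors = FALSE))
  sim <- simulateReads(fx$design, truth,
                       em = cleanQuals(dropoutFactor = 1),
                       depths = c(ampA = 150L, ampB = 150L), seed = 85)
  asn <- assignReads(sim$reads, fx$design)
  aln <- alignReads(sim$reads, asn, fx$design)
  trm <- trimPrimers(aln$aligned, fx$design)
  pile <- pileupReads(trm, reportableRange(fx$design))
  cand <- callVariants(pile, fx$ref, filterConfig(),
                       reportable = reportableRange(fx$design))
  expect_gte(nrow(cand), 1L)
  path <- tempfile(fileext = ".vcf")
  writeVariantVcf(cand, fx$ref, path)
  v <- VariantAnnotation::readVcf(path)
  expect_equal(nrow(v), nrow(cand))
  expect_equal(BiocGenerics::start(SummarizedExperiment::rowRanges(v)),
               cand$pos)
  expect_equal(as.character(VariantAnnotation::ref(v)), cand$ref)
  expect_equal(VariantAnnotation::info(v)$DP, cand$depth)
  expect_equal(VariantAnnotation::info(v)$AF, cand$allele_ratio,
               tolerance = 1e-5)
})
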