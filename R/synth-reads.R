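# Amplicon read simulator. The physically decisive detail: read bases over
# a primer footprint always report the primer sequence as synthesized,
# never the sample allele -- the primer is incorporated into every product,
# which is what makes untrimmed pileups reference-biased and primer
# trimming necessary.

#' Sample ground truth for the read simulator
#'
#' Variants use VCF-style left-anchored keys: an insertion has
#' \code{ref = "A", alt = "ACTTC"}; a deletion \code{ref = "AG",
#' alt = "A"}. \code{mosaic_fraction} is the probability a read carries the
#' allele: fixed at 0.5 for het and 1.0 for hom.
#'
#' @param variants data.frame with columns \code{contig, pos, ref, alt,
#'   zygosity} (het/hom/mosaic) and optional \code{mosaic_fraction}
#'   (required for mosaic) and \code{hap} (1 or 2, default 2; het variants
#'   sharing a hap co-segregate).
#' @param cnvs data.frame with \code{contig, start, end, copy_state}
#'   (het_del/hom_del/gain/high_gain), or NULL.
#' @return list of class \code{SampleTruth}.
#' @export
sampleTruth <- function(variants = NULL, cnvs = NULL) {
  if (is.null(variants))
    variants <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           zygosity = character(),
                           mosaic_fraction = numeric(),
                           hap = integer(), stringsAsFactors = FALSE)
  if (is.null(variants$mosaic_fraction))
    variants$mosaic_fraction <- NA_real_
  if (is.null(variants$hap)) variants$hap <- 2L
  variants$mosaic_fraction[variants$zygosity == "het"] <- 0.5
  variants$mosaic_fraction[variants$zygosity == "hom"] <- 1.0
  if (nrow(variants)) {
    stopifnot(all(variants$zygosity %in% c("het", "hom", "mosaic")),
              all(!is.na(variants$mosaic_fraction)),
              all(variants$mosaic_fraction > 0 &
                  variants$mosaic_fraction <= 1))
    if (anyDuplicated(paste(variants$contig, variants$pos)))
      stop("variant positions must be unique")
  }
  if (is.null(cnvs))
    cnvs <- data.frame(contig = character(), start = integer(),
                       end = integer(), copy_state = character(),
                       stringsAsFactors = FALSE)
  structure(list(variants = variants, cnvs = cnvs),
            class = "SampleTruth")
}

#' Sequencing error and depth model
#'
#' Per-base qualities are drawn from \code{qualLevels} with
#' \code{qualProbs}; a base substitutes to a uniformly random other base
#' with probability \code{10^(-Q/10)} (set \code{errorScale = 0} for
#' error-free reads). Per-amplicon depths are log-normal with mean
#' \code{meanDepth} and coefficient of variation \code{depthCV}
#' (\code{depthCV = 0} gives fixed depths). \code{dropoutFactor} multiplies
#' the yield of reads whose haplotype carries a variant under the
#' amplicon's primer footprint; 0 models complete allele drop-out, 1 a
#' polymorphism that does not impair priming.
#'
#' @param qualLevels,qualProbs Phred quality distribution.
#' @param errorScale multiplier on the quality-implied substitution rate.
#' @param meanDepth,depthCV per-amplicon depth distribution.
#' @param dropoutFactor allele-specific yield factor in [0, 1].
#' @return list of class \code{ErrorModel}.
#' @export
errorModel <- function(qualLevels = c(12L, 22L, 32L, 37L),
                       qualProbs = c(0.02, 0.08, 0.50, 0.40),
                       errorScale = 1, meanDepth = 500, depthCV = 0.3,
                       dropoutFactor = 0) {
  stopifnot(length(qualLevels) == length(qualProbs),
            abs(sum(qualProbs) - 1) < 1e-8, errorScale >= 0,
            meanDepth > 0, depthCV >= 0,
            dropoutFactor >= 0, dropoutFactor <= 1)
  structure(list(qualLevels = as.integer(qualLevels),
                 qualProbs = qualProbs, errorScale = errorScale,
                 meanDepth = meanDepth, depthCV = depthCV,
                 dropoutFactor = dropoutFactor), class = "ErrorModel")
}

applyVariants <- function(tmpl, offset, vars) {
  # vars: rows of truth$variants to apply; offset = ref pos of tmpl[1]
  if (!nrow(vars)) return(tmpl)
  vars <- vars[order(-vars$pos), , drop = FALSE]
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i] - offset + 1L
    rl <- nchar(vars$ref[i])
    stopifnot(substr(tmpl, p, p + rl - 1L) == vars$ref[i])
    tmpl <- paste0(substr(tmpl, 1L, p - 1L), vars$alt[i],
                   substr(tmpl, p + rl, nchar(tmpl)))
  }
  tmpl
}

revcompChr <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgtN", "TGCAtgcaN", x))))
}

revStr <- function(x) intToUtf8(rev(utf8ToInt(x)))

#' Simulate tiled-amplicon reads with recorded ground truth
#'
#' For each amplicon a depth is drawn, each read draws a haplotype (and,
#' independently, carrier status for each mosaic variant at its fraction),
#' and the read sequence is taken from the amplicon product of that
#' haplotype: primer footprints always show the primer sequence, insert
#' bases show the sample alleles. If a truth variant falls under an
#' amplicon's primer footprint, reads of the carrying haplotype from that
#' amplicon are retained with probability \code{dropoutFactor} (allele
#' drop-out). Quality-dependent substitution errors are then injected.
#'
#' @param design a \linkS4class{PanelDesign}.
#' @param truth a \code{SampleTruth}.
#' @param em an \code{ErrorModel}.
#' @param readLen read length; reads longer than the product run into the
#'   adapter tail.
#' @param paired generate forward and reverse reads (half each);
#'   \code{FALSE} gives forward reads only.
#' @param alleleAssignment \code{"random"} draws haplotypes binomially;
#'   \code{"deterministic"} splits reads into exact allele counts
#'   (\code{round(fraction * depth)}), for fixtures needing exact ratios.
#' @param includeTails prepend the adapter tail to each read (5' of the
#'   primer), exercising adapter clipping during assignment.
#' @param decoyFraction fraction of the final read set that is random
#'   off-panel sequence.
#' @param depths optional named vector of fixed per-amplicon depths
#'   overriding the depth model.
#' @param seed integer seed; bit-reproducible output.
#' @return list with \code{reads} (data.frame: read_id, amplicon, mate,
#'   strand, seq, qual), \code{depths} (drawn depth per amplicon),
#'   \code{truth}, and \code{uncapturable} (truth variants no amplicon
#'   insert covers).
#' @export
simulateReads <- function(design, truth, em = errorModel(),
                          readLen = 150L, paired = TRUE,
                          alleleAssignment = c("random", "deterministic"),
                          includeTails = FALSE, decoyFraction = 0,
                          depths = NULL, seed = 1L) {
  alleleAssignment <- match.arg(alleleAssignment)
  stopifnot(is(design, "PanelDesign"), inherits(truth, "SampleTruth"),
            inherits(em, "ErrorModel"), readLen >= 30L)
  set.seed(childSeed(seed, 3L))
  amp <- amplicons(design)
  ins <- ampliconInserts(design)
  ref <- refSequence(design)
  vars <- truth$variants
  # truth variants no insert covers are uncapturable
  uncap <- integer(0)
  if (nrow(vars)) {
    vgr <- GRanges(vars$contig,
                   IRanges(vars$pos, vars$pos + nchar(vars$ref) - 1L))
    uncap <- which(!overlapsAny(vgr, ins, ignore.strand = TRUE))
    if (length(uncap))
      warning(length(uncap), " truth variant(s) not covered by any ",
              "amplicon insert; recorded as uncapturable")
  }
  out <- vector("list", length(amp))
  depth_drawn <- integer(length(amp))
  names(depth_drawn) <- mcols(amp)$id
  for (i in seq_along(amp)) {
    aid <- mcols(amp)$id[i]
    ctg <- as.character(seqnames(amp))[i]
    d <- if (!is.null(depths) && aid %in% names(depths)) {
      as.integer(depths[[aid]])
    } else if (em$depthCV == 0) {
      as.integer(round(em$meanDepth))
    } else {
      s <- sqrt(log(1 + em$depthCV^2))
      as.integer(round(stats::rlnorm(1, log(em$meanDepth) - s^2 / 2, s)))
    }
    depth_drawn[i] <- d
    if (d == 0L) next
    # variants touching this amplicon
    av <- if (nrow(vars)) vars[vars$contig == ctg &
        vars$pos + nchar(vars$ref) - 1L >= start(amp)[i] &
        vars$pos <= end(amp)[i], , drop = FALSE] else vars
    in_insert <- logical(nrow(av))
    if (nrow(av))
      in_insert <- av$pos >= start(ins)[i] &
        av$pos + nchar(av$ref) - 1L <= end(ins)[i]
    # per-read carrier status for each touching variant
    carried <- matrix(FALSE, nrow = d, ncol = nrow(av))
    if (nrow(av)) {
      hap <- if (alleleAssignment == "random") {
        sample(c(1L, 2L), d, replace = TRUE)
      } else {
        rep_len(c(2L, 1L), d)
      }
      for (v in seq_len(nrow(av))) {
        carried[, v] <- switch(av$zygosity[v],
          hom = TRUE,
          het = hap == av$hap[v],
          mosaic = if (alleleAssignment == "random") {
            stats::runif(d) < av$mosaic_fraction[v]
          } else {
            seq_len(d) <= round(av$mosaic_fraction[v] * d)
          })
      }
    }
    # allele drop-out: carrying a variant under this amplicon's primer
    keep <- rep(TRUE, d)
    under_primer <- which(!in_insert)
    for (v in under_primer) {
      hit <- carried[, v]
      if (em$dropoutFactor == 0) keep[hit] <- FALSE
      else if (em$dropoutFactor < 1)
        keep[hit] <- keep[hit] & stats::runif(sum(hit)) < em$dropoutFactor
    }
    carried <- carried[keep, seq_len(nrow(av)), drop = FALSE]
    n <- sum(keep)
    if (n == 0L) next
    # group reads by carried-variant class to build each template once
    applied <- carried[, in_insert, drop = FALSE]
    key <- if (ncol(applied)) apply(applied, 1, paste, collapse = "")
           else rep("", n)
    outer_t <- as.character(subseq(ref[[ctg]], start(amp)[i], end(amp)[i]))
    fl <- mcols(amp)$fwd_len[i]; rl <- mcols(amp)$rev_len[i]
    reads_i <- vector("list", length(unique(key)))
    ki <- 0L
    for (kcls in unique(key)) {
      ki <- ki + 1L
      sel <- which(key == kcls)
      use <- av[in_insert, , drop = FALSE][
        if (ncol(applied)) applied[sel[1], ] else logical(0), ,
        drop = FALSE]
      tmpl <- outer_t
      if (nrow(use)) {
        # apply to the insert only; primer footprints keep the primer
        ins_seq <- substr(tmpl, fl + 1L, nchar(tmpl) - rl)
        ins_seq <- applyVariants(ins_seq, start(ins)[i], use)
        tmpl <- paste0(substr(tmpl, 1L, fl), ins_seq,
                       substr(tmpl, nchar(outer_t) - rl + 1L,
                              nchar(outer_t)))
      }
      fwd_ext <- paste0(if (includeTails) mcols(amp)$fwd_tail[i] else "",
                        tmpl, revcompChr(mcols(amp)$rev_tail[i]))
      rev_ext <- paste0(if (includeTails) mcols(amp)$rev_tail[i] else "",
                        revcompChr(tmpl),
                        revcompChr(mcols(amp)$fwd_tail[i]))
      is_rev <- if (paired) seq_along(sel) %% 2L == 0L
                else rep(FALSE, length(sel))
      seqs <- ifelse(is_rev,
                     substr(rev_ext, 1L, min(readLen, nchar(rev_ext))),
                     substr(fwd_ext, 1L, min(readLen, nchar(fwd_ext))))
      reads_i[[ki]] <- data.frame(
        read_id = paste0(aid, ":", sel),
        amplicon = aid, mate = ifelse(is_rev, 2L, 1L),
        strand = ifelse(is_rev, "-", "+"), seq = seqs,
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, reads_i)
  }
  reads <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                            list(make.row.names = FALSE)))
  if (is.null(reads))
    reads <- data.frame(read_id = character(), amplicon = character(),
                        mate = integer(), strand = character(),
                        seq = character(), stringsAsFactors = FALSE)
  # decoy off-panel reads
  if (decoyFraction > 0 && nrow(reads)) {
    n_dec <- round(decoyFraction / (1 - decoyFraction) * nrow(reads))
    if (n_dec > 0) {
      dec <- vapply(seq_len(n_dec), function(j) randomDna(readLen),
                    character(1))
      reads <- rbind(reads, data.frame(
        read_id = paste0("decoy:", seq_len(n_dec)),
        amplicon = NA_character_, mate = 1L, strand = "+", seq = dec,
        stringsAsFactors = FALSE))
    }
  }
  # qualities and substitution errors, vectorized over all reads
  reads$qual <- ""
  if (nrow(reads)) {
    lens <- nchar(reads$seq)
    tot <- sum(lens)
    q <- em$qualLevels[sample.int(length(em$qualLevels), tot,
                                  replace = TRUE, prob = em$qualProbs)]
    ridx <- rep.int(seq_len(nrow(reads)), lens)
    chars <- strsplit(paste(reads$seq, collapse = ""), "")[[1]]
    if (em$errorScale > 0) {
      perr <- pmin(1, em$errorScale * 10^(-q / 10))
      hit <- which(stats::runif(tot) < perr)
      if (length(hit)) {
        alt4 <- c("A", "C", "G", "T")
        for (h in hit) {
          others <- alt4[alt4 != chars[h]]
          chars[h] <- others[sample.int(3L, 1L)]
        }
      }
    }
    qchars <- intToUtf8(q + 33L, multiple = TRUE)
    reads$seq <- vapply(split(chars, ridx), paste, character(1),
                        collapse = "")
    reads$qual <- vapply(split(qchars, ridx), paste, character(1),
                         collapse = "")
  }
  list(reads = reads, depths = depth_drawn, truth = truth,
       uncapturable = if (nrow(vars)) vars[uncap, , drop = FALSE]
                      else vars)
}

#' Write / read simulated reads as FASTQ (Sanger Phred+33)
#'
#' Paired simulations are written as \code{<prefix>_R1.fastq} /
#' \code{<prefix>_R2.fastq}; single-end as \code{<prefix>.fastq}.
#'
#' @param sim result of [simulateReads()], or any data.frame with
#'   \code{read_id, seq, qual} (and optional \code{mate}).
#' @param prefix output path prefix.
#' @return invisibly, the file path(s) written.
#' @export
writeReadsFastq <- function(sim, prefix) {
  reads <- if (is.data.frame(sim)) sim else sim$reads
  wr <- function(df, path) {
    x <- DNAStringSet(df$seq)
    names(x) <- df$read_id
    writeXStringSet(x, path, format = "fastq",
                    qualities = Biostrings::BStringSet(df$qual))
    path
  }
  if (!is.null(reads$mate) && any(reads$mate == 2L)) {
    paths <- c(wr(reads[reads$mate == 1L, ], paste0(prefix, "_R1.fastq")),
               wr(reads[reads$mate == 2L, ], paste0(prefix, "_R2.fastq")))
  } else {
    paths <- wr(reads, paste0(prefix, ".fastq"))
  }
  invisible(paths)
}

#' @rdname writeReadsFastq
#' @param paths FASTQ file path(s); mate number is taken from the order.
#' @export
readReadsFastq <- function(paths) {
  parts <- lapply(seq_along(paths), function(i) {
    x <- readDNAStringSet(paths[i], format = "fastq", with.qualities = TRUE)
    data.frame(read_id = names(x), amplicon = NA_character_,
               mate = i, strand = NA_character_,
               seq = as.character(x),
               qual = as.character(mcols(x)$qualities),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}
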