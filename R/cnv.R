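# Exon-resolution copy-number calling on aCGH probe log2-ratio tracks:
# centralization (mode-to-zero), optional GC regression, scan-statistic
# segmentation, fuzzy-zero pruning of long low-amplitude segments, and
# threshold classification of aberrations.

#' aCGH analysis configuration
#'
#' The aberration filter follows the assay's clinical settings: at least
#' 4 probes per called region, |mean log2| at least 0.35 for a single-copy
#' gain and 0.45 for a heterozygous deletion; mean log2 above 0.6 is a
#' high copy gain and below -1 a homozygous loss. The segmentation scan
#' keeps intervals whose score |mean|*sqrt(n)/sd reaches
#' \code{segScoreThresh}. Fuzzy-zero pruning removes segments with
#' \code{|mean| < z * sd * (a + b/sqrt(n))}, modelling residual long-range
#' correlated noise that per-probe sd underestimates.
#'
#' @param minProbes minimum probes per called aberration.
#' @param gainThresh,hetDelThresh,highGainThresh,homDelThresh mean-log2
#'   classification thresholds.
#' @param segScoreThresh segmentation score threshold.
#' @param fuzzyZero enable fuzzy-zero pruning.
#' @param fzZ,fzA,fzB fuzzy-zero constants (z, a, b).
#' @return list of class \code{AcghConfig}.
#' @export
acghConfig <- function(minProbes = 4L, gainThresh = 0.35,
                       hetDelThresh = -0.45, highGainThresh = 0.6,
                       homDelThresh = -1.0, segScoreThresh = 6.0,
                       fuzzyZero = TRUE, fzZ = 3, fzA = 0.25, fzB = 1.0) {
  stopifnot(homDelThresh < hetDelThresh, hetDelThresh < 0,
            0 < gainThresh, gainThresh < highGainThresh, minProbes >= 1)
  structure(list(minProbes = as.integer(minProbes),
                 gainThresh = gainThresh, hetDelThresh = hetDelThresh,
                 highGainThresh = highGainThresh,
                 homDelThresh = homDelThresh,
                 segScoreThresh = segScoreThresh, fuzzyZero = fuzzyZero,
                 fzZ = fzZ, fzA = fzA, fzB = fzB), class = "AcghConfig")
}

#' Estimate probe noise sd (derivative MAD)
#'
#' Median absolute successive difference of log2 values within each
#' contig, scaled by 1/(sqrt(2) * 0.6745); robust to true copy-number
#' events, which contribute only two jumps each.
#'
#' @param track a \linkS4class{ProbeTrack}.
#' @return the track with \code{noiseSd} filled in.
#' @export
estimateNoiseSd <- function(track) {
  df <- probes(track)
  d <- unlist(lapply(split(df$log2, df$contig), diff), use.names = FALSE)
  if (!length(d)) stop("need at least 2 probes on one contig")
  sd <- stats::median(abs(d)) / (sqrt(2) * 0.6745)
  track@noiseSd <- max(sd, 1e-6)
  track
}

#' Centralize a track: shift the log2 mode to zero
#'
#' The copy-neutral state dominates any targeted track, so the mode of the
#' log2 distribution (kernel density estimate) identifies the neutral
#' level even when a sizeable minority of probes sit in aberrations; the
#' whole track is shifted so this mode lands at zero.
#'
#' @param track a \linkS4class{ProbeTrack} (at least 20 probes).
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return the shifted track; the applied shift accumulates in the
#'   \code{shift} slot.
#' @export
centralize <- function(track, bw = "nrd0") {
  df <- probes(track)
  if (nrow(df) < 20L)
    stop("centralization needs at least 20 probes, got ", nrow(df))
  den <- stats::density(df$log2, bw = bw)
  mode <- den$x[which.max(den$y)]
  df$log2 <- df$log2 - mode
  track@probes <- df
  track@shift <- track@shift - mode
  track
}

#' Optional GC correction
#'
#' When per-probe GC fractions are supplied, removes the linear trend of
#' log2 on GC (fit on all probes); otherwise returns the track unchanged.
#'
#' @param track a \linkS4class{ProbeTrack}.
#' @param gc numeric vector of per-probe GC fractions aligned with
#'   \code{probes(track)}, or NULL.
#' @return the corrected track.
#' @export
correctGc <- function(track, gc = NULL) {
  if (is.null(gc)) return(track)
  df <- probes(track)
  stopifnot(length(gc) == nrow(df))
  fit <- stats::lm(df$log2 ~ gc)
  df$log2 <- df$log2 - (stats::fitted(fit) - mean(df$log2))
  track@probes <- df
  track
}

# best-scoring interval within x[lo..hi]; score = |mean| * sqrt(n) / sd
bestInterval <- function(cs, lo, hi, sd) {
  # cs = c(0, cumsum(x)); interval [i..j] sum = cs[j+1] - cs[i]
  best <- list(score = -Inf)
  for (i in lo:hi) {
    j <- i:hi
    s <- abs(cs[j + 1L] - cs[i]) / sqrt(j - i + 1L) / sd
    k <- which.max(s)
    if (s[k] > best$score)
      best <- list(from = i, to = i + k - 1L, score = s[k])
  }
  best
}

#' Segment a probe track by recursive scan-statistic splitting
#'
#' Within each contig, the interval maximizing
#' \code{|mean(log2)| * sqrt(n) / noise_sd} is located; if its score
#' reaches \code{segScoreThresh} it is recorded as a segment and the scan
#' recurses into the flanks. Adjacent same-sign segments are then merged.
#' Probes outside every returned segment form the neutral baseline.
#'
#' @param track a \linkS4class{ProbeTrack}; noise sd is estimated with
#'   [estimateNoiseSd()] if not yet set.
#' @param config an \code{AcghConfig}.
#' @return data.frame of segments: \code{contig, from, to} (global probe
#'   row indices into \code{probes(track)}), \code{start, end} (genomic),
#'   \code{n_probes, mean_log2, score}.
#' @export
segmentTrack <- function(track, config = acghConfig()) {
  if (is.na(noiseSd(track))) track <- estimateNoiseSd(track)
  sd <- noiseSd(track)
  stopifnot(sd > 0)
  df <- probes(track)
  segs <- list()
  recurse <- function(cs, lo, hi, collect) {
    if (hi < lo) return(collect)
    b <- bestInterval(cs, lo, hi, sd)
    if (b$score < config$segScoreThresh) return(collect)
    collect[[length(collect) + 1L]] <- c(b$from, b$to, b$score)
    collect <- recurse(cs, lo, b$from - 1L, collect)
    recurse(cs, b$to + 1L, hi, collect)
  }
  for (ctg in unique(df$contig)) {
    rows <- which(df$contig == ctg)
    x <- df$log2[rows]
    cs <- c(0, cumsum(x))
    found <- recurse(cs, 1L, length(x), list())
    if (!length(found)) next
    m <- do.call(rbind, found)
    m <- m[order(m[, 1]), , drop = FALSE]
    # greedy merge of adjacent same-sign intervals
    i <- 1L
    while (i < nrow(m)) {
      mean_i <- (cs[m[i, 2] + 1L] - cs[m[i, 1]]) / (m[i, 2] - m[i, 1] + 1)
      mean_j <- (cs[m[i + 1L, 2] + 1L] - cs[m[i + 1L, 1]]) /
        (m[i + 1L, 2] - m[i + 1L, 1] + 1)
      if (m[i, 2] + 1L == m[i + 1L, 1] && sign(mean_i) == sign(mean_j)) {
        m[i, 2] <- m[i + 1L, 2]
        m <- m[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    n <- m[, 2] - m[, 1] + 1
    mu <- (cs[m[, 2] + 1L] - cs[m[, 1]]) / n
    segs[[length(segs) + 1L]] <- data.frame(
      contig = ctg, from = rows[m[, 1]], to = rows[m[, 2]],
      start = df$pos[rows[m[, 1]]], end = df$pos[rows[m[, 2]]],
      n_probes = as.integer(n), mean_log2 = mu,
      score = abs(mu) * sqrt(n) / sd, stringsAsFactors = FALSE)
  }
  if (!length(segs)) return(emptySegments())
  out <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  out[order(out$contig, out$from), , drop = FALSE]
}

emptySegments <- function() {
  data.frame(contig = character(), from = integer(), to = integer(),
             start = integer(), end = integer(), n_probes = integer(),
             mean_log2 = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Fuzzy-zero pruning of long low-amplitude segments
#'
#' Long segments can reach a high scan score with a mean log2 too small to
#' be a real copy-number state, because long-range correlated noise is not
#' captured by the per-probe sd. A segment is removed when
#' \code{|mean_log2| < z * sd * (a + b / sqrt(n))}; short high-amplitude
#' segments are unaffected. Disabled via \code{fuzzyZero = FALSE}, which
#' returns the input unchanged.
#'
#' @param segments data.frame from [segmentTrack()].
#' @param track the \linkS4class{ProbeTrack} the segments came from.
#' @param config an \code{AcghConfig}.
#' @return the pruned segment data.frame.
#' @export
fuzzyZero <- function(segments, track, config = acghConfig()) {
  if (!config$fuzzyZero || !nrow(segments)) return(segments)
  if (is.na(noiseSd(track))) track <- estimateNoiseSd(track)
  sd <- noiseSd(track)
  bound <- config$fzZ * sd *
    (config$fzA + config$fzB / sqrt(segments$n_probes))
  out <- segments[abs(segments$mean_log2) >= bound, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify segments into copy-number aberration calls
#'
#' Applies the aberration filter: segments with fewer than
#' \code{minProbes} probes or mean log2 inside the neutral band
#' \code{(hetDelThresh, gainThresh)} are dropped; the rest classify as
#' \code{high_gain} (mean > highGainThresh), \code{gain}, \code{het_del}
#' (homDelThresh <= mean <= hetDelThresh) or \code{hom_del}
#' (mean < homDelThresh).
#'
#' @param segments data.frame of (pruned) segments.
#' @param config an \code{AcghConfig}.
#' @return the segment data.frame with an added \code{class} column.
#' @export
callAberrations <- function(segments, config = acghConfig()) {
  if (!nrow(segments)) {
    segments$class <- character(0)
    return(segments)
  }
  keep <- segments$n_probes >= config$minProbes &
    (segments$mean_log2 >= config$gainThresh |
     segments$mean_log2 <= config$hetDelThresh)
  out <- segments[keep, , drop = FALSE]
  out$class <- ifelse(out$mean_log2 > config$highGainThresh, "high_gain",
                ifelse(out$mean_log2 >= config$gainThresh, "gain",
                 ifelse(out$mean_log2 < config$homDelThresh, "hom_del",
                        "het_del")))
  rownames(out) <- NULL
  out
}

#' Annotate aberration calls with overlapped exons
#'
#' @param calls data.frame from [callAberrations()].
#' @param targetExons \code{GRanges} with gene/exon columns.
#' @return calls with added \code{exons} (comma-separated
#'   \code{GENE:ex<N>} labels, empty for intronic-only calls),
#'   \code{n_exons}, \code{width_bp} and a human-readable \code{label}
#'   such as \code{"G3:ex13 del, ~2.0 kb"}.
#' @export
annotateExons <- function(calls, targetExons) {
  if (!nrow(calls)) {
    calls$exons <- character(0); calls$n_exons <- integer(0)
    calls$width_bp <- integer(0); calls$label <- character(0)
    return(calls)
  }
  cgr <- GRanges(calls$contig, IRanges(calls$start, calls$end))
  hits <- findOverlaps(cgr, targetExons, ignore.strand = TRUE)
  lab <- paste0(mcols(targetExons)$gene, ":ex", mcols(targetExons)$exon)
  exlist <- vapply(seq_along(cgr), function(i) {
    h <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    paste(lab[h], collapse = ",")
  }, character(1))
  calls$exons <- exlist
  calls$n_exons <- ifelse(nzchar(exlist),
                          lengths(strsplit(exlist, ",")), 0L)
  calls$width_bp <- calls$end - calls$start + 1L
  kind <- ifelse(calls$mean_log2 < 0, "del", "dup")
  calls$label <- sprintf("%s %s, ~%.1f kb",
                         ifelse(nzchar(exlist), exlist, calls$contig),
                         kind, calls$width_bp / 1000)
  calls
}

#' Run the full CNV pipeline on a probe track
#'
#' Convenience wrapper: noise estimation, centralization, optional GC
#' correction, segmentation, fuzzy-zero pruning, aberration calling and
#' exon annotation.
#'
#' @param track a \linkS4class{ProbeTrack}.
#' @param targetExons \code{GRanges} of exons (for annotation), or NULL.
#' @param config an \code{AcghConfig}.
#' @param gc optional per-probe GC fractions.
#' @return list with \code{track} (processed), \code{segments},
#'   \code{calls}.
#' @export
runCnvPipeline <- function(track, targetExons = NULL,
                           config = acghConfig(), gc = NULL) {
  track <- estimateNoiseSd(track)
  track <- centralize(track)
  track <- correctGc(track, gc)
  segs <- segmentTrack(track, config)
  segs <- fuzzyZero(segs, track, config)
  calls <- callAberrations(segs, config)
  if (!is.null(targetExons)) calls <- annotateExons(calls, targetExons)
  list(track = track, segments = segs, calls = calls)
}
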