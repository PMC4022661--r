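# aCGH probe-track simulation: exon-dense probe placement (a fixed number
# of probes per exon) plus intronic backbone probes at a regular spacing,
# with log2 ratios set by the overlapping copy-number state plus Gaussian
# noise. Two-channel intensities are not modelled; log2 ratios are
# generated directly.

#' Construct a ProbeTrack
#'
#' @param df data.frame with columns \code{probe_id, contig, pos, log2}
#'   (any order; will be sorted by contig then position).
#' @param noiseSd optional known noise sd; left \code{NA} to be estimated
#'   later by [estimateNoiseSd()].
#' @return a \linkS4class{ProbeTrack}.
#' @export
probeTrack <- function(df, noiseSd = NA_real_) {
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new("ProbeTrack", probes = df, noiseSd = noiseSd, shift = 0)
}

#' Simulate an aCGH probe track with known copy-number truth
#'
#' Places \code{probesPerExon} evenly spaced probes in every target exon
#' and backbone probes every \code{intronSpacing} bases between exons,
#' then sets each probe's log2 ratio to the value of its copy state
#' (neutral probes 0) plus \code{rnorm(0, noiseSd)}.
#'
#' @param targetExons \code{GRanges} of exons (as from [makeReference()]).
#' @param cnvs data.frame with \code{contig, start, end, copy_state}; may
#'   have zero rows for a neutral genome.
#' @param probesPerExon probes placed per exon (default 13).
#' @param intronSpacing intronic probe spacing in bp (default 2500).
#' @param trueLog2 named vector mapping copy states to noise-free log2
#'   ratios. The het-deletion default is -0.7 rather than the theoretical
#'   -1: single-copy losses in practice sit well above -1, which is also
#'   what keeps them inside the het-del classification band.
#' @param noiseSd Gaussian probe noise sd.
#' @param seed integer seed.
#' @return list with \code{track} (\linkS4class{ProbeTrack}) and
#'   \code{truth} (the cnv table).
#' @export
simulateAcgh <- function(targetExons, cnvs = NULL, probesPerExon = 13L,
                         intronSpacing = 2500L,
                         trueLog2 = c(neutral = 0, het_del = -0.7,
                                      hom_del = -2.5, gain = 0.45,
                                      high_gain = 1.0),
                         noiseSd = 0.15, seed = 1L) {
  stopifnot(probesPerExon >= 1L, noiseSd >= 0)
  if (is.null(cnvs))
    cnvs <- data.frame(contig = character(), start = integer(),
                       end = integer(), copy_state = character(),
                       stringsAsFactors = FALSE)
  stopifnot(all(cnvs$copy_state %in% names(trueLog2)))
  set.seed(childSeed(seed, 4L))
  rows <- list()
  for (ctg in unique(as.character(seqnames(targetExons)))) {
    ex <- BiocGenerics::sort(targetExons[seqnames(targetExons) == ctg])
    for (i in seq_along(ex)) {
      p <- unique(as.integer(round(
        seq(start(ex)[i], end(ex)[i], length.out = probesPerExon))))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, pos = p, stringsAsFactors = FALSE)
      if (i < length(ex)) {
        gap_lo <- end(ex)[i] + 1L
        gap_hi <- start(ex)[i + 1L] - 1L
        if (gap_hi - gap_lo + 1L >= intronSpacing) {
          ip <- seq(gap_lo + intronSpacing %/% 2L, gap_hi,
                    by = intronSpacing)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = ctg, pos = as.integer(ip), stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  log2v <- rep(trueLog2[["neutral"]], nrow(df))
  if (nrow(cnvs)) {
    pg <- GRanges(df$contig, IRanges(df$pos, df$pos))
    cg <- GRanges(cnvs$contig, IRanges(cnvs$start, cnvs$end))
    hits <- findOverlaps(pg, cg, ignore.strand = TRUE)
    log2v[S4Vectors::queryHits(hits)] <-
      trueLog2[cnvs$copy_state[S4Vectors::subjectHits(hits)]]
  }
  if (noiseSd > 0) log2v <- log2v + stats::rnorm(nrow(df), 0, noiseSd)
  track <- probeTrack(data.frame(
    probe_id = sprintf("P%05d", seq_len(nrow(df))),
    contig = df$contig, pos = df$pos, log2 = log2v,
    stringsAsFactors = FALSE))
  list(track = track, truth = cnvs)
}

#' Read / write a probe track as TSV
#'
#' Columns \code{probe_id, contig, pos, log2}, tab-separated with header.
#' @param path file path.
#' @param track a \linkS4class{ProbeTrack}.
#' @return \code{readProbeTrack} returns a \linkS4class{ProbeTrack}.
#' @export
readProbeTrack <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "contig", "pos", "log2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("probe track ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  probeTrack(df[, need])
}

#' @rdname readProbeTrack
#' @export
writeProbeTrack <- function(track, path) {
  utils::write.table(probes(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
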