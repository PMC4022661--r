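# Assay-performance metrics: analytical sensitivity and specificity with
# the clinical formulas, per-sample outcome classification and cohort
# summaries.

#' Analytical sensitivity
#'
#' TP / (TP + FN) over variant keys: the fraction of truth variants
#' present in the called set.
#'
#' @param truthKeys character vector of expected variant keys (non-empty).
#' @param calledKeys character vector of called variant keys.
#' @return sensitivity as a percentage.
#' @export
assaySensitivity <- function(truthKeys, calledKeys) {
  truthKeys <- unique(truthKeys)
  if (!length(truthKeys)) stop("truth set is empty")
  tp <- sum(truthKeys %in% calledKeys)
  100 * tp / length(truthKeys)
}

#' Analytical specificity (per-base)
#'
#' True calls are read as correctly wild-type interrogated positions, so
#' specificity = (interrogated - FP) / interrogated. The display value is
#' truncated (not rounded) to two decimals, so e.g. 30 false positives
#' over 5,788,250 interrogated bases gives 99.99, not 100.00.
#'
#' @param interrogatedBases total base pairs interrogated.
#' @param fpCount number of false-positive calls.
#' @param digits decimals kept in the truncated display value.
#' @return list with \code{percent} (truncated display value) and
#'   \code{exact} (untruncated percentage).
#' @export
assaySpecificity <- function(interrogatedBases, fpCount, digits = 2L) {
  stopifnot(interrogatedBases > 0, fpCount >= 0,
            fpCount <= interrogatedBases)
  exact <- 100 * (interrogatedBases - fpCount) / interrogatedBases
  f <- 10^digits
  list(percent = floor(exact * f) / f, exact = exact)
}

#' Classify a sample from its reportable variants
#'
#' Positive when at least one reportable variant is pathogenic in the
#' lookup table; otherwise inconclusive when at least one is a VUS
#' (variants missing from the table are treated as VUS with a warning);
#' otherwise negative. The driver gene is taken from the first pathogenic
#' variant.
#'
#' @param reportables data.frame with \code{key} and optional \code{gene}
#'   columns (zero rows for a clean sample).
#' @param pathogenicityTable named character vector mapping variant keys
#'   to \code{"pathogenic"}, \code{"VUS"} or \code{"benign"}.
#' @return list of class \code{SampleOutcome}: \code{category}
#'   (positive/inconclusive/negative) and \code{driver_gene} (NA unless
#'   positive).
#' @export
classifySample <- function(reportables, pathogenicityTable) {
  if (!nrow(reportables))
    return(structure(list(category = "negative",
                          driver_gene = NA_character_),
                     class = "SampleOutcome"))
  cls <- pathogenicityTable[reportables$key]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)),
            " variant(s) missing from the pathogenicity table; ",
            "treated as VUS")
    cls[is.na(cls)] <- "VUS"
  }
  if (any(cls == "pathogenic")) {
    first <- which(cls == "pathogenic")[1]
    gene <- if ("gene" %in% names(reportables))
      reportables$gene[first] else NA_character_
    structure(list(category = "positive", driver_gene = gene),
              class = "SampleOutcome")
  } else if (any(cls == "VUS")) {
    structure(list(category = "inconclusive",
                   driver_gene = NA_character_),
              class = "SampleOutcome")
  } else {
    structure(list(category = "negative", driver_gene = NA_character_),
              class = "SampleOutcome")
  }
}

#' Cohort summary rates and per-gene distribution of positives
#'
#' @param outcomes list of \code{SampleOutcome} objects, or a character
#'   vector of categories.
#' @return list with \code{n}, \code{counts}, \code{rates} (percent, one
#'   decimal, names positive/inconclusive/negative) and \code{per_gene}
#'   (table of driver genes among positives).
#' @export
cohortSummary <- function(outcomes) {
  if (!length(outcomes)) stop("no outcomes")
  if (is.character(outcomes)) {
    cats <- outcomes
    genes <- character(0)
  } else {
    cats <- vapply(outcomes, `[[`, character(1), "category")
    genes <- vapply(outcomes, `[[`, character(1), "driver_gene")
    genes <- genes[cats == "positive" & !is.na(genes)]
  }
  lv <- c("positive", "inconclusive", "negative")
  stopifnot(all(cats %in% lv))
  counts <- table(factor(cats, levels = lv))
  rates <- round(100 * as.numeric(counts) / length(cats), 1)
  names(rates) <- lv
  list(n = length(cats), counts = counts, rates = rates,
       per_gene = if (length(genes)) table(genes) else table(character(0)))
}
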