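#' Risk classification thresholds
#'
#' Interval bounds mapping an overall interaction score to a risk class:
#' High when score >= `high_min` (0.75), Moderate when `moderate_min`
#' (0.5) <= score < `high_min`, Low below `moderate_min`.
#'
#' @param high_min lower (closed) bound of the High class.
#' @param moderate_min lower (closed) bound of the Moderate class.
#' @return Object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(high_min = 0.75, moderate_min = 0.5) {
  stopifnot(0 < moderate_min, moderate_min < high_min, high_min <= 1)
  structure(list(high_min = high_min, moderate_min = moderate_min),
            class = "risk_thresholds")
}

#' Classify an overall interaction score into a risk level
#'
#' Partitions \[0, 1\] exactly: every score maps to exactly one of High,
#' Moderate, Low, with closed lower boundaries (0.75 is High, 0.5 is
#' Moderate). Monotone in the score.
#'
#' @param score numeric vector of overall scores in \[0, 1\].
#' @param thresholds a [risk_thresholds()].
#' @return Character vector of levels in \{High, Moderate, Low\}.
#' @export
#' @examples
#' classify_score(c(0.85, 0.65, 0.46))
classify_score <- function(score, thresholds = risk_thresholds()) {
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  ifelse(score >= thresholds$high_min, "High",
         ifelse(score >= thresholds$moderate_min, "Moderate", "Low"))
}

#' Aggregate pairwise risk levels into a combination-level label
#'
#' The most severe level among a combination's drug pairs becomes the
#' combination's label (High > Moderate > Low > Unknown). A single-drug
#' combination has no pairs and is labeled None. Order-invariant and
#' idempotent under duplication of labels.
#'
#' @param pair_levels character vector of pairwise risk levels (possibly
#'   empty).
#' @return A single risk level.
#' @export
aggregate_combination_risk <- function(pair_levels) {
  if (length(pair_levels) == 0L) return("None")
  names(RISK_LEVELS)[max(risk_severity(pair_levels)) + 1L]
}

#' Label mined combinations with risk levels
#'
#' For each combination every unordered drug pair is looked up in the
#' curated risk table and the pair levels are aggregated by maximum
#' severity ([aggregate_combination_risk()]). When no risk table is
#' supplied but a `score` column is present, labels fall back to
#' [classify_score()] on the combination's overall score; a curated table
#' takes precedence when both are available.
#'
#' @param combos `data.frame` with a `combination` column of canonical
#'   keys (e.g. from [select_high_frequency()]).
#' @param risks a [risk_table()], or `NULL` to classify from scores.
#' @param thresholds a [risk_thresholds()] (used only for the score
#'   fallback).
#' @return `combos` with a `risk_level` column appended.
#' @export
label_combinations <- function(combos, risks = NULL,
                               thresholds = risk_thresholds()) {
  stopifnot(is.data.frame(combos), "combination" %in% names(combos))
  if (is.null(risks)) {
    if (!"score" %in% names(combos)) {
      stop("either a risk table or a score column is required for labeling")
    }
    combos$risk_level <- classify_score(combos$score, thresholds)
    return(combos)
  }
  stopifnot(inherits(risks, "risk_table"))
  tuples <- combo_drugs(combos$combination)
  combos$risk_level <- vapply(tuples, function(drugs) {
    if (length(drugs) < 2L) return("None")
    pairs <- utils::combn(drugs, 2L)
    aggregate_combination_risk(risk_lookup(risks, pairs[1L, ], pairs[2L, ]))
  }, "")
  combos
}
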