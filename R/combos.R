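## Canonical combination keys: drugs sorted in radix (C-locale) order and
## joined by "|". Normalized names never contain "|", so keys are unique.

#' Canonical key for a drug combination
#'
#' @param drugs character vector of normalized drug names (any order).
#' @return Single string: the drugs sorted lexicographically, joined by "|".
#' @export
combo_key <- function(drugs) {
  paste(sort_c(unique(drugs)), collapse = "|")
}

#' Split a combination key back into its drugs
#'
#' @param key character vector of combination keys.
#' @return List of character vectors (one per key).
#' @export
combo_drugs <- function(key) {
  strsplit(key, "|", fixed = TRUE)
}

#' Construct an admission drug set
#'
#' One hospitalization's de-duplicated, normalized drug set - the unit of
#' combination mining.
#'
#' @param subject_id,hadm_id opaque identifiers (coerced to character,
#'   never parsed).
#' @param drugs character vector of drug names; normalized unless
#'   `normalize = FALSE`.
#' @param normalize apply [normalize_drug_name()]? Default `TRUE`.
#' @return An object of class `admission_drug_set`: a list with
#'   `subject_id`, `hadm_id` and the sorted unique `drugs`.
#' @export
admission_drug_set <- function(subject_id, hadm_id, drugs, normalize = TRUE) {
  if (normalize) drugs <- normalize_drug_name(drugs)
  drugs <- sort_c(unique(drugs))
  if (length(drugs) < 1L) stop("an admission needs at least one drug")
  structure(
    list(subject_id = as.character(subject_id),
         hadm_id = as.character(hadm_id),
         drugs = drugs),
    class = "admission_drug_set"
  )
}

#' @export
print.admission_drug_set <- function(x, ...) {
  cat("<admission ", x$subject_id, "/", x$hadm_id, "> ",
      paste(x$drugs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate all 1-4 drug combinations of an admission
#'
#' Generates every subset of size 1 up to `max_combo_size` of the
#' admission's drug set, each in canonical (sorted, "|"-joined) form. The
#' number of tuples equals the sum of binomial coefficients
#' choose(n, 1..max).
#'
#' @param drugs an `admission_drug_set` or a character vector of
#'   normalized drug names.
#' @param config a [mining_config()]; only `max_combo_size` is used.
#' @return Character vector of canonical combination keys.
#' @export
#' @examples
#' enumerate_combinations(c("aspirin", "warfarin", "heparin"))
enumerate_combinations <- function(drugs, config = mining_config()) {
  if (inherits(drugs, "admission_drug_set")) drugs <- drugs$drugs
  drugs <- sort_c(unique(drugs))
  n <- length(drugs)
  if (n < 1L) stop("an admission needs at least one drug")
  kmax <- min(config$max_combo_size, n)
  keys <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    m <- utils::combn(drugs, k)
    ## columns are already in sorted order because the input is sorted
    keys[[k]] <- if (k == 1L) drugs else apply(m, 2L, paste, collapse = "|")
  }
  unlist(keys, use.names = FALSE)
}
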