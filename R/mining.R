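#' Mining configuration
#'
#' Parameters of the frequency-mining stage: combinations of 1 up to
#' `max_combo_size` drugs are enumerated per admission, combinations seen
#' in fewer than `min_frequency` admissions are discarded as chance
#' co-occurrences, and only the `top_n` most frequent survivors are kept.
#'
#' @param max_combo_size largest tuple size enumerated (default 4).
#' @param min_frequency minimum admission count to retain (default 4).
#' @param top_n cap on the ranked list (default 30000).
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(max_combo_size = 4L, min_frequency = 4L,
                          top_n = 30000L) {
  stopifnot(max_combo_size >= 1L, min_frequency >= 1L, top_n >= 1L)
  structure(list(max_combo_size = as.integer(max_combo_size),
                 min_frequency = as.integer(min_frequency),
                 top_n = as.integer(top_n)),
            class = "mining_config")
}

#' Count combination frequencies across a corpus of admissions
#'
#' Every admission contributes at most once to each combination it
#' contains, so no combination's count can exceed the number of
#' admissions. With `per_subject = TRUE` a subject's admissions are first
#' collapsed to their union drug set, making the subject the counting unit
#' (a sensitivity variant; the default unit is the admission).
#'
#' @param admissions list of [admission_drug_set()] objects.
#' @param config a [mining_config()].
#' @param per_subject collapse admissions per subject before counting?
#' @return Object of class `combo_counter`: a named integer vector of
#'   admission counts keyed by canonical combination key.
#' @export
count_combination_frequencies <- function(admissions,
                                          config = mining_config(),
                                          per_subject = FALSE) {
  if (length(admissions) == 0L) stop("no admissions to mine")
  if (per_subject) {
    subj <- vapply(admissions, function(a) a$subject_id, "")
    admissions <- lapply(split(admissions, subj), function(as) {
      admission_drug_set(as[[1L]]$subject_id, "union",
                         unlist(lapply(as, function(a) a$drugs)),
                         normalize = FALSE)
    })
  }
  keys <- unlist(lapply(admissions, enumerate_combinations, config = config),
                 use.names = FALSE)
  tab <- table(keys)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(counts, class = "combo_counter",
            n_admissions = length(admissions),
            max_combo_size = config$max_combo_size)
}

#' @export
print.combo_counter <- function(x, ...) {
  cat("<combo_counter> ", length(x), " combination(s) over ",
      attr(x, "n_admissions"), " admission(s)\n", sep = "")
  invisible(x)
}

#' Frequency of a combination in a counter
#'
#' @param counter a `combo_counter`.
#' @param key canonical combination key(s) ([combo_key()]).
#' @return Integer counts; 0 for combinations never observed.
#' @export
counter_frequency <- function(counter, key) {
  out <- unclass(counter)[key]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Drugs observed in a counter
#'
#' The size-1 combinations, i.e. every drug occurring in the corpus; the
#' default candidate universe of the recommender.
#'
#' @param counter a `combo_counter`.
#' @return Sorted character vector of drug names.
#' @export
counter_universe <- function(counter) {
  keys <- names(counter)
  sort_c(keys[!grepl("|", keys, fixed = TRUE)])
}

#' Select the high-frequency combinations
#'
#' Drops combinations seen fewer than `min_frequency` times, sorts the
#' survivors by frequency (descending; ties broken lexicographically on
#' the canonical key), and truncates to the `top_n` head. Filtering
#' precedes the cap. The result is a deterministic function of the
#' counter.
#'
#' @param counter a `combo_counter`.
#' @param config a [mining_config()].
#' @return `data.frame` with columns `combination` (canonical key),
#'   `size` and `frequency`, in rank order; zero rows if nothing
#'   qualifies.
#' @export
select_high_frequency <- function(counter, config = mining_config()) {
  keep <- unclass(counter) >= config$min_frequency
  keys <- names(counter)[keep]
  freq <- unname(unclass(counter)[keep])
  ord <- order_c(-freq, keys)
  keys <- keys[ord]
  freq <- freq[ord]
  n <- min(length(keys), config$top_n)
  keys <- keys[seq_len(n)]
  freq <- freq[seq_len(n)]
  data.frame(
    combination = keys,
    size = lengths(combo_drugs(keys)),
    frequency = as.integer(freq),
    stringsAsFactors = FALSE
  )
}

#' Write a mined combination table
#'
#' Emits COMBINATION (drugs "|"-joined in canonical order), SIZE,
#' FREQUENCY, plus any extra columns present (e.g. RISK_LEVEL).
#'
#' @param combos data.frame from [select_high_frequency()] or
#'   [label_combinations()].
#' @param path output path.
#' @param sep field separator; tab by default (the keys contain "|").
#' @export
write_combinations <- function(combos, path, sep = "\t") {
  df <- combos
  names(df) <- toupper(names(df))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mined combination table
#'
#' @param path path written by [write_combinations()].
#' @param sep field separator.
#' @return `data.frame` with lower-cased column names.
#' @export
read_combinations <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("COMBINATION", "SIZE", "FREQUENCY"), sep)
  names(df) <- tolower(names(df))
  df$size <- as.integer(df$size)
  df$frequency <- as.integer(df$frequency)
  df
}
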