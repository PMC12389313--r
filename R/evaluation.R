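#' Top-k recommendation metrics
#'
#' Standard top-k retrieval metrics, averaged over evaluation cases. Per
#' case, with hits = |top-k of recommended n relevant|: precision@k =
#' hits / k; recall@k = hits / |relevant|; F1@k = harmonic mean of
#' precision and recall (0 when both are 0); hit@k = 1 if hits >= 1 else
#' 0.
#'
#' @param cases list of cases, each a list with elements `relevant`
#'   (non-empty character vector of held-out ground-truth drugs) and
#'   `recommended` (ordered character vector, no duplicates).
#' @param k list cut-off (>= 1).
#' @return Named list: `precision`, `recall`, `f1`, `hit` (means across
#'   cases, on the 0-1 scale) and `n_cases`.
#' @export
topk_metrics <- function(cases, k = 10L) {
  stopifnot(k >= 1L)
  if (length(cases) == 0L) stop("no evaluation cases supplied")
  per_case <- vapply(cases, function(case) {
    rel <- unique(case$relevant)
    if (length(rel) == 0L) stop("an evaluation case has no relevant drugs")
    rec <- case$recommended
    if (anyDuplicated(rec)) stop("recommended list contains duplicates")
    hits <- length(intersect(utils::head(rec, k), rel))
    p <- hits / k
    r <- hits / length(rel)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1, hit = as.numeric(hits >= 1))
  }, numeric(4))
  means <- rowMeans(per_case)
  list(precision = means[["precision"]], recall = means[["recall"]],
       f1 = means[["f1"]], hit = means[["hit"]],
       n_cases = length(cases))
}

#' Evaluate the recommender by leave-one-drug-out on a held-out split
#'
#' Splits the admissions into a training fraction (default 80%) and a
#' test remainder with a seeded shuffle, trains the combination counter
#' on the training split, and for every test admission with at least two
#' drugs holds out one drug as ground truth (by default the
#' lexicographically last; `holdout = "random"` samples it), recommends
#' from the remaining drugs, and aggregates [topk_metrics()] over the
#' cases. Deterministic given the seed.
#'
#' @param admissions list of [admission_drug_set()] objects (>= 5).
#' @param genes a [drug_gene_map()]; default: empty map (frequency-only
#'   recommendation).
#' @param risks a [risk_table()]; default: empty table (no penalties).
#' @param split_fraction training fraction in (0, 1).
#' @param seed integer seed for the split (and the holdout draw when
#'   random).
#' @param k top-k cut-off.
#' @param holdout `"last"` (default) or `"random"`.
#' @param config a [mining_config()] for the training counter.
#' @param weights a [recommendation_weights()].
#' @param penalties a [penalty_table()].
#' @return The [topk_metrics()] list, plus `n_train` and `n_test`.
#' @export
evaluate_model <- function(admissions, genes = drug_gene_map(),
                           risks = risk_table(), split_fraction = 0.8,
                           seed = 1L, k = 10L,
                           holdout = c("last", "random"),
                           config = mining_config(),
                           weights = recommendation_weights(),
                           penalties = penalty_table()) {
  holdout <- match.arg(holdout)
  stopifnot(split_fraction > 0, split_fraction < 1)
  if (length(admissions) < 5L) {
    stop("need at least 5 admissions to split and evaluate")
  }
  with_seed(seed, {
    perm <- sample.int(length(admissions))
    n_train <- max(1L, floor(split_fraction * length(admissions)))
    train <- admissions[perm[seq_len(n_train)]]
    test <- admissions[perm[-seq_len(n_train)]]
    if (length(test) == 0L) stop("split leaves no test admissions")
    counter <- count_combination_frequencies(train, config)
    universe <- counter_universe(counter)
    cases <- list()
    for (adm in test) {
      if (length(adm$drugs) < 2L) next
      held <- if (holdout == "last") {
        adm$drugs[length(adm$drugs)]  # drugs are sorted; last = lex max
      } else {
        sample(adm$drugs, 1L)
      }
      input <- setdiff(adm$drugs, held)
      recs <- recommend_candidates(input, counter, genes, risks,
                                   universe = universe, weights = weights,
                                   penalties = penalties, k = k)
      cases[[length(cases) + 1L]] <-
        list(relevant = held, recommended = recs$candidate)
    }
    if (length(cases) == 0L) {
      stop("no test admission has >= 2 drugs; nothing to evaluate")
    }
    m <- topk_metrics(cases, k)
    m$n_train <- length(train)
    m$n_test <- length(test)
    m
  })
}
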