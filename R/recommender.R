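## The greedy recommendation core: candidates from the observed drug
## universe are scored against an input combination by
##   total = alpha * frequency + beta * gene overlap + gamma * risk penalty
## and ranked; substitution additionally constrains the candidate's risk
## against the remaining context to at most the replaced drug's.

#' Recommendation weights
#'
#' Default weights of the combined recommendation score: frequency 1.0,
#' gene overlap 2.0, risk penalty 1.0 (the configuration that minimized
#' mean squared recommendation error in the model's weight scan).
#'
#' @param alpha_freq weight of the co-occurrence frequency term.
#' @param beta_gene weight of the shared-target-gene term.
#' @param gamma_risk weight of the (non-positive) risk-penalty term.
#' @return Object of class `recommendation_weights`.
#' @export
recommendation_weights <- function(alpha_freq = 1.0, beta_gene = 2.0,
                                   gamma_risk = 1.0) {
  stopifnot(alpha_freq >= 0, beta_gene >= 0, gamma_risk >= 0)
  structure(list(alpha_freq = alpha_freq, beta_gene = beta_gene,
                 gamma_risk = gamma_risk),
            class = "recommendation_weights")
}

#' Risk penalty table
#'
#' Penalty points accrued per interaction pair by risk level: High -10,
#' Moderate -5, Low -1; Unknown and None pairs carry no penalty.
#'
#' @param High,Moderate,Low,Unknown,None penalty per pair at each level
#'   (all must be <= 0, strictly decreasing with severity among
#'   Low/Moderate/High).
#' @return Named numeric vector of class `penalty_table`.
#' @export
penalty_table <- function(High = -10, Moderate = -5, Low = -1,
                          Unknown = 0, None = 0) {
  p <- c(High = High, Moderate = Moderate, Low = Low,
         Unknown = Unknown, None = None)
  stopifnot(all(p <= 0), High < Moderate, Moderate < Low)
  structure(p, class = "penalty_table")
}

#' Frequency score of a candidate against an input combination
#'
#' Sums, over every non-empty subset S of the input combination with at
#' most two drugs, the corpus frequency of the 2-3 tuple formed by S plus
#' the candidate. Tuples never observed contribute 0.
#'
#' @param candidate a drug name not in `input_combo`.
#' @param input_combo character vector of input drugs.
#' @param counter a `combo_counter` from
#'   [count_combination_frequencies()].
#' @return Non-negative count sum.
#' @export
frequency_score <- function(candidate, input_combo, counter) {
  stopifnot(!candidate %in% input_combo)
  keys <- character(0)
  n <- length(input_combo)
  if (n >= 1L) {
    keys <- vapply(input_combo, function(d) combo_key(c(d, candidate)), "")
  }
  if (n >= 2L) {
    pairs <- utils::combn(input_combo, 2L)
    keys <- c(keys, apply(pairs, 2L,
                          function(p) combo_key(c(p, candidate))))
  }
  sum(counter_frequency(counter, keys))
}

#' Gene-overlap score of a candidate
#'
#' Accumulates the shared-target count |genes(candidate) n genes(d)| over
#' every input drug d.
#'
#' @inheritParams frequency_score
#' @param genes a [drug_gene_map()].
#' @return Non-negative count sum.
#' @export
gene_overlap_score <- function(candidate, input_combo, genes) {
  stopifnot(!candidate %in% input_combo)
  gc <- gene_targets(genes, candidate)
  if (length(gc) == 0L) return(0L)
  sum(vapply(input_combo,
             function(d) length(intersect(gc, gene_targets(genes, d))),
             integer(1)))
}

#' Risk penalty of a candidate
#'
#' Looks up the interaction level of each (candidate, input drug) pair in
#' the risk table and accumulates the corresponding penalty points.
#'
#' @inheritParams frequency_score
#' @param risks a [risk_table()].
#' @param penalties a [penalty_table()].
#' @return Non-positive penalty sum.
#' @export
risk_penalty <- function(candidate, input_combo, risks,
                         penalties = penalty_table()) {
  stopifnot(!candidate %in% input_combo)
  levels <- risk_lookup(risks, rep(candidate, length(input_combo)),
                        input_combo)
  sum(unclass(penalties)[levels])
}

#' Combined recommendation score
#'
#' `alpha * frequency + beta * gene overlap + gamma * risk penalty` with
#' the supplied weights; exact arithmetic, bit-for-bit recomputable from
#' the components.
#'
#' @param frequency,gene_overlap,risk_penalty the three score components.
#' @param weights a [recommendation_weights()].
#' @return Weighted total (vectorized).
#' @export
total_score <- function(frequency, gene_overlap, risk_penalty,
                        weights = recommendation_weights()) {
  weights$alpha_freq * frequency + weights$beta_gene * gene_overlap +
    weights$gamma_risk * risk_penalty
}

#' Jaccard similarity of two drugs' target-gene sets
#'
#' |intersection| / |union|; defined as 0 when both gene sets are empty.
#' The mechanistic-similarity proxy of the substitution step.
#'
#' @param a,b drug names.
#' @param genes a [drug_gene_map()].
#' @return Value in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b, genes) {
  ga <- gene_targets(genes, a)
  gb <- gene_targets(genes, b)
  u <- length(union(ga, gb))
  if (u == 0L) return(0)
  length(intersect(ga, gb)) / u
}

## 0-100 min-max normalization over a candidate pool, half-up rounding
## (printed recommendation scores are integers); a degenerate pool
## (single candidate, or all totals equal) scores 100.
normalize_pool_scores <- function(total) {
  span <- max(total) - min(total)
  if (length(total) == 0L) return(integer(0))
  if (span == 0) return(rep(100L, length(total)))
  as.integer(floor(100 * (total - min(total)) / span + 0.5))
}

#' Rank candidate drugs against an input combination
#'
#' Scores every candidate in the universe by the combined recommendation
#' score and returns the top `k`, sorted by total (descending, ties
#' broken lexicographically on the drug name). The 0-100 normalized score
#' is a min-max rescale over the scored pool, rounded half-up.
#'
#' @param input_combo character vector of input drugs (normalized).
#' @param counter a `combo_counter`.
#' @param genes a [drug_gene_map()].
#' @param risks a [risk_table()].
#' @param universe candidate drugs; default: every drug observed in the
#'   counter, minus the input combination.
#' @param weights a [recommendation_weights()].
#' @param penalties a [penalty_table()].
#' @param k number of candidates to return (default all).
#' @return `data.frame` with columns `candidate`, `frequency_score`,
#'   `gene_overlap`, `risk_penalty`, `total`, `normalized_score`, in rank
#'   order; zero rows when the universe is empty.
#' @export
recommend_candidates <- function(input_combo, counter, genes, risks,
                                 universe = NULL,
                                 weights = recommendation_weights(),
                                 penalties = penalty_table(),
                                 k = Inf) {
  if (is.null(universe)) universe <- counter_universe(counter)
  universe <- sort_c(setdiff(universe, input_combo))
  if (length(universe) == 0L) {
    return(data.frame(candidate = character(), frequency_score = numeric(),
                      gene_overlap = numeric(), risk_penalty = numeric(),
                      total = numeric(), normalized_score = integer()))
  }
  fs <- vapply(universe, frequency_score, numeric(1),
               input_combo = input_combo, counter = counter)
  go <- vapply(universe, gene_overlap_score, numeric(1),
               input_combo = input_combo, genes = genes)
  rp <- vapply(universe, risk_penalty, numeric(1),
               input_combo = input_combo, risks = risks,
               penalties = penalties)
  tot <- total_score(fs, go, rp, weights)
  out <- data.frame(candidate = universe, frequency_score = unname(fs),
                    gene_overlap = unname(go), risk_penalty = unname(rp),
                    total = unname(tot),
                    normalized_score = normalize_pool_scores(unname(tot)),
                    stringsAsFactors = FALSE)
  out <- out[order_c(-out$total, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(k)) k else nrow(out))
}

## Max severity of a drug's pairwise interactions with a context set;
## "None" for an empty context.
context_risk_label <- function(drug, context, risks) {
  if (length(context) == 0L) return("None")
  aggregate_combination_risk(
    risk_lookup(risks, rep(drug, length(context)), context))
}

#' Recommend substitutes for a risky drug within a combination
#'
#' Removes `risky_drug` from the combination, scores candidates against
#' the remaining context with the combined recommendation score, keeps
#' only candidates whose own risk label against the context (maximum pair
#' severity) does not exceed the replaced drug's, and attaches the
#' target-gene Jaccard similarity and shared-gene count between each
#' substitute and the replaced drug. The 0-100 score is normalized over
#' the admissible pool.
#'
#' @param risky_drug the drug to replace; must be in `context_combo`.
#' @param context_combo the full input combination including
#'   `risky_drug`.
#' @inheritParams recommend_candidates
#' @return `data.frame` with columns `risk_drug`, `substitute`,
#'   `similarity`, `shared_genes`, `score` (0-100), `total`,
#'   `frequency_score`, `gene_overlap`, `risk_penalty`, `original_risk`,
#'   `substitute_risk`, in rank order; zero rows when no candidate is
#'   admissible.
#' @export
recommend_substitute <- function(risky_drug, context_combo, counter, genes,
                                 risks, universe = NULL,
                                 weights = recommendation_weights(),
                                 penalties = penalty_table(),
                                 k = Inf) {
  if (!risky_drug %in% context_combo) {
    stop(sQuote(risky_drug), " is not part of the input combination")
  }
  context <- setdiff(context_combo, risky_drug)
  original_risk <- context_risk_label(risky_drug, context, risks)
  if (is.null(universe)) universe <- counter_universe(counter)
  universe <- sort_c(setdiff(universe, context_combo))
  sub_risk <- vapply(universe, context_risk_label, "",
                     context = context, risks = risks)
  keep <- risk_severity(sub_risk) <= risk_severity(original_risk)
  pool <- universe[keep]
  sub_risk <- sub_risk[keep]
  scored <- recommend_candidates(context, counter, genes, risks,
                                 universe = pool, weights = weights,
                                 penalties = penalties)
  if (nrow(scored) == 0L) {
    return(data.frame(risk_drug = character(), substitute = character(),
                      similarity = numeric(), shared_genes = integer(),
                      score = integer(), total = numeric(),
                      frequency_score = numeric(), gene_overlap = numeric(),
                      risk_penalty = numeric(), original_risk = character(),
                      substitute_risk = character()))
  }
  sim <- vapply(scored$candidate, jaccard_similarity, numeric(1),
                b = risky_drug, genes = genes)
  shared <- vapply(scored$candidate, function(cand) {
    length(intersect(gene_targets(genes, cand),
                     gene_targets(genes, risky_drug)))
  }, integer(1))
  out <- data.frame(
    risk_drug = risky_drug,
    substitute = scored$candidate,
    similarity = unname(sim),
    shared_genes = unname(shared),
    score = scored$normalized_score,
    total = scored$total,
    frequency_score = scored$frequency_score,
    gene_overlap = scored$gene_overlap,
    risk_penalty = scored$risk_penalty,
    original_risk = original_risk,
    substitute_risk = unname(sub_risk[scored$candidate]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(k)) k else nrow(out))
}
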