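# Independent brute-force oracles. These deliberately avoid the package's
# enumeration/lookup machinery: tuples are generated from the corpus-wide
# drug union and membership is checked admission by admission.

# All candidate tuples (sizes 1..max_size) over a drug universe, as
# canonical keys.
oracle_all_tuples <- function(drugs, max_size = 4L) {
  drugs <- sort(unique(drugs), method = "radix")
  out <- character(0)
  for (k in seq_len(min(max_size, length(drugs)))) {
    m <- utils::combn(drugs, k)
    out <- c(out, apply(m, 2L, paste, collapse = "|"))
  }
  out
}

# Count, for every candidate tuple, the number of admissions whose drug
# set contains it (each admission contributes at most once).
oracle_count <- function(admissions, max_size = 4L) {
  all_drugs <- unlist(lapply(admissions, function(a) a$drugs))
  tuples <- oracle_all_tuples(all_drugs, max_size)
  counts <- vapply(tuples, function(key) {
    members <- strsplit(key, "|", fixed = TRUE)[[1L]]
    sum(vapply(admissions, function(a) all(members %in% a$drugs), logical(1)))
  }, integer(1))
  counts[counts > 0L]
}

# Score one candidate by direct re-derivation of the weighted total:
# frequency by re-counting admissions containing each (subset + candidate)
# tuple, overlap and penalty by straight loops.
oracle_candidate_total <- function(candidate, input_combo, admissions,
                                   genes, risks, weights, penalties,
                                   max_size = 4L) {
  freq <- 0L
  subsets <- list()
  for (d in input_combo) subsets[[length(subsets) + 1L]] <- d
  if (length(input_combo) >= 2L) {
    m <- utils::combn(input_combo, 2L)
    for (j in seq_len(ncol(m))) subsets[[length(subsets) + 1L]] <- m[, j]
  }
  for (s in subsets) {
    tuple <- c(s, candidate)
    if (length(tuple) <= max_size) {
      freq <- freq + sum(vapply(admissions,
                                function(a) all(tuple %in% a$drugs),
                                logical(1)))
    }
  }
  overlap <- 0L
  for (d in input_combo) {
    overlap <- overlap + length(intersect(gene_targets(genes, candidate),
                                          gene_targets(genes, d)))
  }
  pen <- 0
  for (d in input_combo) {
    pen <- pen + unclass(penalties)[[risk_lookup(risks, candidate, d)]]
  }
  weights$alpha_freq * freq + weights$beta_gene * overlap +
    weights$gamma_risk * pen
}

# Exhaustive ranking of a candidate universe by the oracle total,
# total-descending then name-ascending.
oracle_rank <- function(input_combo, universe, admissions, genes, risks,
                        weights = recommendation_weights(),
                        penalties = penalty_table()) {
  universe <- sort(setdiff(universe, input_combo), method = "radix")
  tot <- vapply(universe, oracle_candidate_total, numeric(1),
                input_combo = input_combo, admissions = admissions,
                genes = genes, risks = risks, weights = weights,
                penalties = penalties)
  ord <- order(-tot, universe, method = "radix")
  data.frame(candidate = universe[ord], total = unname(tot[ord]))
}

# Small random instance: <= n_adm admissions over <= n_drugs drugs.
random_instance <- function(seed, n_adm = 8L, n_drugs = 8L) {
  set.seed(seed)
  drugs <- letters[seq_len(sample(2:n_drugs, 1L))]
  n <- sample(seq_len(n_adm), 1L)
  lapply(seq_len(n), function(i) {
    admission_drug_set(sprintf("s%02d", i), "h1",
                       sample(drugs, sample(seq_along(drugs), 1L)),
                       normalize = FALSE)
  })
}

empty_gene_map <- function() drug_gene_map()
empty_risk_table <- function() risk_table()
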