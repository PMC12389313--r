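test_that("generators are byte-identical for identical seeds", {
  spec <- cohort_spec(n_subjects = 15, seed = 4)
  expect_identical(gen_cohort(spec), gen_cohort(spec))
  u <- sprintf("d%02d", 1:10)
  expect_identical(gen_drug_gene_map(u, seed = 2),
                   gen_drug_gene_map(u, seed = 2))
  expect_identical(gen_risk_table(u, risk_mix_spec(seed = 2)),
                   gen_risk_table(u, risk_mix_spec(seed = 2)))
  expect_identical(gen_docking_modes(seed = 2), gen_docking_modes(seed = 2))
  # generation leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_cohort(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted combinations reach at least their target frequency", {
  spec <- cohort_spec(
    n_subjects = 40,
    planted_combos = list(list(drugs = c("pa", "pb"), frequency = 6),
                          list(drugs = c("pc", "pd", "pe"), frequency = 4)),
    seed = 11
  )
  ctr <- count_combination_frequencies(gen_cohort(spec))
  expect_gte(counter_frequency(ctr, "pa|pb"), 6L)
  expect_gte(counter_frequency(ctr, "pc|pd|pe"), 4L)
  expect_error(cohort_spec(planted_combos = list(
    list(drugs = letters[1:5], frequency = 2))), "1-4")
  bad <- cohort_spec(n_subjects = 2, admissions_per_subject = c(1, 1),
                     planted_combos = list(list(drugs = "x",
                                                frequency = 50)))
  expect_error(gen_cohort(bad), "exceeds")
})

test_that("rank-frequency curves decay and steepen with the Zipf exponent", {
  shallow <- cohort_spec(n_subjects = 120, zipf_exponent = 0.8, seed = 8)
  steep <- cohort_spec(n_subjects = 120, zipf_exponent = 2.2, seed = 8)
  freq_curve <- function(spec) {
    ctr <- count_combination_frequencies(gen_cohort(spec),
                                         mining_config(max_combo_size = 1))
    sort(as.integer(ctr), decreasing = TRUE)
  }
  f1 <- freq_curve(shallow)
  f2 <- freq_curve(steep)
  expect_true(all(diff(f1) <= 0))  # sorted curve is non-increasing
  # rank-1 share of all prescriptions grows with the exponent
  expect_gt(f2[1] / sum(f2), f1[1] / sum(f1))
})

test_that("planted gene overlaps give the predicted Jaccard similarity", {
  u <- c("a", "b", "c", "d")
  gm <- gen_drug_gene_map(u, shared_gene_blocks = list(
    list(pair = c("a", "b"), overlap = 7, set_sizes = c(10, 10)),
    list(pair = c("c", "d"), overlap = 0, set_sizes = c(5, 5))
  ), seed = 6)
  expect_equal(jaccard_similarity("a", "b", gm), 7 / 13)
  expect_equal(jaccard_similarity("c", "d", gm), 0)  # planted disjoint
  # a drug planted in two blocks keeps both intersection counts exact
  gm2 <- gen_drug_gene_map(u, shared_gene_blocks = list(
    list(pair = c("a", "b"), overlap = 7, set_sizes = c(10, 10)),
    list(pair = c("a", "c"), overlap = 2, set_sizes = c(6, 6))
  ), seed = 6)
  expect_length(intersect(gene_targets(gm2, "a"), gene_targets(gm2, "b")), 7)
  expect_length(intersect(gene_targets(gm2, "a"), gene_targets(gm2, "c")), 2)
  expect_error(gen_drug_gene_map(u, shared_gene_blocks = list(
    list(pair = c("a", "b"), overlap = 9, set_sizes = c(5, 10)))),
    "exceeds")
})

test_that("risk-table mixtures converge to their specification", {
  u <- sprintf("d%03d", 1:150)  # ~11k pairs
  rt <- gen_risk_table(u, risk_mix_spec(seed = 12))
  share <- table(rt$levels) / length(rt$levels)
  expect_lt(abs(share[["Moderate"]] - 21829 / 30000), 0.03)
  expect_lt(abs(share[["Unknown"]] - 6127 / 30000), 0.03)
  # degenerate mixture
  pure <- risk_mix_spec(c(High = 0, Moderate = 1, Low = 0, Unknown = 0,
                          None = 0), seed = 1)
  rt2 <- gen_risk_table(letters[1:8], pure)
  expect_true(all(rt2$levels == "Moderate"))
})

test_that("generated docking runs honor the reference-mode convention", {
  for (seed in 1:10) {
    m <- gen_docking_modes(n_modes = sample(1:9, 1), seed = seed)
    expect_identical(m$rmsd[m$mode == 1L], 0)
    expect_equal(m$affinity[m$mode == 1L], min(m$affinity))
    norm <- normalize_modes(m)
    expect_equal(norm$normalized_affinity[norm$mode == 1L], 1.0)
    expect_equal(norm$inverse_normalized_rmsd[norm$mode == 1L], 1.0)
  }
})

test_that("the full pipeline runs end to end on generated inputs", {
  spec <- cohort_spec(
    n_subjects = 60, drug_universe_size = 40,
    planted_combos = list(list(drugs = c("pa", "pb"), frequency = 8)),
    seed = 21
  )
  adm <- gen_cohort(spec)
  ctr <- count_combination_frequencies(adm)
  hf <- select_high_frequency(ctr, mining_config(min_frequency = 4,
                                                 top_n = 500))
  expect_true(all(hf$frequency >= 4))
  universe <- counter_universe(ctr)
  gm <- gen_drug_gene_map(universe, seed = 22)
  rt <- gen_risk_table(universe, risk_mix_spec(seed = 23), n_pairs = 400)
  lab <- label_combinations(hf, rt)
  expect_true(all(lab$risk_level %in% risk_levels()))
  g <- build_dgin(lab, gm)
  s <- network_stats(g)
  expect_gt(s$drug_nodes, 0L)
  # docking-derived scores for one pair stay in [0, 1]
  pair_run <- gen_docking_modes(seed = 24)
  expect_true(pair_interaction_score(pair_run) >= 0 &&
              pair_interaction_score(pair_run) <= 1)
  # recommendation over the mined corpus
  recs <- recommend_candidates(c("pa"), ctr, gm, rt, k = 10)
  expect_lte(nrow(recs), 10L)
  expect_true("pb" %in% recs$candidate[1:3])  # planted co-occurrer ranks high
  m <- evaluate_model(adm, gm, rt, seed = 25, k = 10,
                      config = mining_config(min_frequency = 1))
  expect_true(all(unlist(m[c("precision", "recall", "f1", "hit")]) >= 0))
})
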