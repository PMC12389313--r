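make_counter <- function(counts) {
  structure(as.integer(counts), names = names(counts),
            class = "combo_counter", n_admissions = max(counts),
            max_combo_size = 4L)
}

test_that("frequency score accumulates the 2-3 tuple counts", {
  ctr <- make_counter(c("a|c" = 7))
  expect_equal(frequency_score("c", "a", ctr), 7)
  ctr2 <- make_counter(c("a|c" = 3, "b|c" = 2, "a|b|c" = 4))
  expect_equal(frequency_score("c", c("a", "b"), ctr2), 9)
  expect_equal(frequency_score("z", c("a", "b"), ctr2), 0)
  expect_error(frequency_score("a", c("a", "b"), ctr2))
})

test_that("gene overlap accumulates shared-target counts per input drug", {
  gm <- drug_gene_map(c("c", "c", "a", "a", "b", "b"),
                      c("G1", "G2", "G2", "G3", "G1", "G2"),
                      normalize = FALSE)
  expect_equal(gene_overlap_score("c", "a", gm), 1)
  expect_equal(gene_overlap_score("c", c("a", "b"), gm), 3)
  expect_equal(gene_overlap_score("z", c("a", "b"), gm), 0)
})

test_that("risk penalties accumulate the per-level points", {
  rt <- risk_table(c("c", "c"), c("a", "b"), c("High", "Moderate"),
                   normalize = FALSE)
  expect_equal(risk_penalty("c", "a", rt), -10)
  expect_equal(risk_penalty("c", c("a", "b"), rt), -15)
  expect_equal(risk_penalty("z", c("a", "b"), rt), 0)  # Unknown pairs: 0
  expect_error(penalty_table(High = -1, Moderate = -5))  # severity ordering
})

test_that("the weighted total reproduces the default-weight arithmetic", {
  expect_equal(total_score(1, 0, 0), 1.0)
  expect_equal(total_score(0, 1, 0), 2.0)
  expect_equal(total_score(2, 3, -5), 3.0)
  w <- recommendation_weights(0.5, 1.5, 2)
  expect_equal(total_score(2, 2, -1, w), 0.5 * 2 + 1.5 * 2 - 2)
})

test_that("Jaccard similarity handles identity, disjoint and empty sets", {
  gm <- drug_gene_map(c("a", "a", "b", "b", "c", "d", "d", "d"),
                      c("G1", "G2", "G1", "G2", "G3", "G1", "G4", "G5"),
                      normalize = FALSE)
  expect_equal(jaccard_similarity("a", "b", gm), 1.0)
  expect_equal(jaccard_similarity("a", "c", gm), 0.0)
  expect_equal(jaccard_similarity("a", "d", gm), 0.25)  # 1 shared / 4 union
  expect_equal(jaccard_similarity("z", "w", gm), 0.0)   # both empty
  expect_equal(jaccard_similarity("a", "d", gm), jaccard_similarity("d", "a", gm))
})

test_that("candidate ranking matches the brute-force scorer", {
  for (seed in 1:40) {
    adm <- random_instance(seed)
    ctr <- count_combination_frequencies(adm)
    universe <- counter_universe(ctr)
    gm <- gen_drug_gene_map(universe, seed = seed)
    rt <- gen_risk_table(universe, risk_mix_spec(seed = seed))
    set.seed(seed + 1000)
    input <- sample(universe, min(length(universe) - 1L, sample(1:3, 1)))
    got <- recommend_candidates(input, ctr, gm, rt)
    want <- oracle_rank(input, universe, adm, gm, rt)
    expect_identical(got$candidate, want$candidate)
    expect_equal(got$total, want$total)
    # decomposition is bit-exact recomputable
    expect_equal(got$total,
                 total_score(got$frequency_score, got$gene_overlap,
                             got$risk_penalty))
  }
})

test_that("normalized scores are 0-100, affine-invariant, 100 when degenerate", {
  ctr <- make_counter(c(a = 5, b = 3, "a|b" = 2, c = 1,
                        "a|c" = 4, "b|c" = 1))
  gm <- drug_gene_map(normalize = FALSE)
  rt <- risk_table()
  recs <- recommend_candidates("c", ctr, gm, rt)
  expect_true(all(recs$normalized_score >= 0 & recs$normalized_score <= 100))
  expect_identical(recs$normalized_score[1], 100L)
  expect_identical(recs$normalized_score[nrow(recs)], 0L)
  # a single-candidate pool scores 100
  one <- recommend_candidates("c", ctr, gm, rt, universe = c("a", "c"))
  expect_identical(one$normalized_score, 100L)
  # affine invariance: shifting all totals uniformly via the risk weight
  # (every candidate penalised equally) leaves the normalized scores alone
  rt_all <- risk_table(c("a", "b"), c("c", "c"), c("Low", "Low"),
                       normalize = FALSE)
  shifted <- recommend_candidates("c", ctr, gm, rt_all)
  expect_identical(shifted$normalized_score, recs$normalized_score)
})

test_that("higher co-occurrence wins between otherwise identical candidates", {
  ctr <- make_counter(c("a|x" = 5, "a|y" = 3))
  recs <- recommend_candidates("a", ctr, drug_gene_map(), risk_table(),
                               universe = c("x", "y"))
  expect_identical(recs$candidate, c("x", "y"))
  # ties break lexicographically
  ctr2 <- make_counter(c("a|x" = 3, "a|y" = 3))
  recs2 <- recommend_candidates("a", ctr2, drug_gene_map(), risk_table(),
                                universe = c("y", "x"))
  expect_identical(recs2$candidate, c("x", "y"))
})

test_that("total score is monotone in its components", {
  set.seed(21)
  for (i in 1:30) {
    f <- runif(1, 0, 50); g <- runif(1, 0, 20); p <- -runif(1, 0, 15)
    expect_gt(total_score(f + 1, g, p), total_score(f, g, p))
    expect_gt(total_score(f, g + 1, p), total_score(f, g, p))
    # worsening one pair from Low to High lowers the total
    expect_lt(total_score(f, g, p - 9), total_score(f, g, p))
  }
})

test_that("substitutes never exceed the replaced drug's risk severity", {
  ctr <- make_counter(c(a = 9, b = 8, c = 7, d = 6, e = 5))
  gm <- drug_gene_map(normalize = FALSE)
  # b is Moderate with a; candidate c is Low, candidate d is High, e unknown
  rt <- risk_table(c("a", "a", "a"), c("b", "c", "d"),
                   c("Moderate", "Low", "High"), normalize = FALSE)
  subs <- recommend_substitute("b", c("a", "b"), ctr, gm, rt)
  expect_false("d" %in% subs$substitute)  # High > Moderate: filtered out
  expect_setequal(subs$substitute, c("c", "e"))
  expect_true(all(risk_severity(subs$substitute_risk) <=
                  risk_severity(subs$original_risk)))
  expect_error(recommend_substitute("z", c("a", "b"), ctr, gm, rt),
               "not part")
  # every candidate riskier than the original -> empty list
  rt2 <- risk_table(c("a", "a", "a", "a"), c("b", "c", "d", "e"),
                    c("Low", "High", "High", "High"), normalize = FALSE)
  expect_identical(nrow(recommend_substitute("b", c("a", "b"), ctr, gm, rt2)),
                   0L)
})

test_that("a planted low-risk high-overlap substitute is recovered", {
  universe <- c("input1", "orig", "cand", "decoy")
  ctr <- make_counter(stats::setNames(rep(5L, 4), universe))
  # block 1 plants the mechanistic similarity with the replaced drug,
  # block 2 the gene-overlap signal with the remaining context; cand
  # accumulates both blocks (7 + 3 shared genes + 3 + 7 unique = 20)
  gm <- gen_drug_gene_map(universe,
                          shared_gene_blocks = list(
                            list(pair = c("cand", "orig"), overlap = 7,
                                 set_sizes = c(10, 10)),
                            list(pair = c("cand", "input1"), overlap = 3,
                                 set_sizes = c(10, 10))),
                          seed = 3)
  rt <- risk_table(c("orig", "cand"), c("input1", "input1"),
                   c("Moderate", "Low"), normalize = FALSE)
  subs <- recommend_substitute("orig", c("input1", "orig"), ctr, gm, rt)
  expect_identical(subs$substitute[1], "cand")
  expect_identical(subs$shared_genes[1], 7L)
  expect_identical(subs$original_risk[1], "Moderate")
  expect_identical(subs$substitute_risk[1], "Low")
  expect_equal(subs$similarity[1], 7 / (20 + 10 - 7))
  # ordering of the admissible pool equals the brute-force ranking
  adm_equiv <- lapply(universe, function(d)
    admission_drug_set("s", d, d, normalize = FALSE))
  want <- oracle_rank("input1", setdiff(universe, c("input1", "orig")),
                      adm_equiv, gm, rt)
  keep <- want$candidate %in% subs$substitute
  expect_identical(subs$substitute, want$candidate[keep])
})
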