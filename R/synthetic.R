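## Seeded generators for every input the pipeline consumes, with planted
## structure (known frequent combinations, known gene overlaps) so every
## stage has a recoverable ground truth. All randomness flows from the
## spec-level seed through a private RNG stream; global random state is
## never touched.

#' Synthetic cohort specification
#'
#' Parameters of the prescription-record generator. Background drug
#' popularity is Zipf-distributed (probability of rank r proportional to
#' r^-exponent), which reproduces the heavy-tailed, decaying
#' rank-frequency curve characteristic of real co-prescription data.
#' Planted combinations are guaranteed to reach at least their target
#' frequency.
#'
#' @param n_subjects number of subjects.
#' @param admissions_per_subject integer range (min, max) of admissions
#'   drawn per subject.
#' @param drug_universe_size number of background drugs.
#' @param planted_combos list of `list(drugs = <1-4 names>, frequency =
#'   <target count>)` entries.
#' @param background_set_size integer range (min, max) of background
#'   drugs per admission.
#' @param zipf_exponent decay exponent of the background popularity
#'   distribution (> 0).
#' @param seed integer seed fixing the entire output.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        admissions_per_subject = c(1L, 3L),
                        drug_universe_size = 60L,
                        planted_combos = list(),
                        background_set_size = c(3L, 10L),
                        zipf_exponent = 1.5,
                        seed = 1L) {
  stopifnot(n_subjects >= 1L, drug_universe_size >= 1L, zipf_exponent > 0,
            length(admissions_per_subject) == 2L,
            admissions_per_subject[1L] >= 1L,
            admissions_per_subject[1L] <= admissions_per_subject[2L],
            length(background_set_size) == 2L,
            background_set_size[1L] >= 1L,
            background_set_size[1L] <= background_set_size[2L])
  for (pc in planted_combos) {
    stopifnot(is.list(pc), !is.null(pc$drugs), !is.null(pc$frequency))
    if (length(pc$drugs) < 1L || length(pc$drugs) > 4L) {
      stop("planted combinations must contain 1-4 drugs")
    }
    stopifnot(pc$frequency >= 1L)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 admissions_per_subject = as.integer(admissions_per_subject),
                 drug_universe_size = as.integer(drug_universe_size),
                 planted_combos = planted_combos,
                 background_set_size = as.integer(background_set_size),
                 zipf_exponent = zipf_exponent,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Drug universe of a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return Character vector of background drug names (`drug001`, ...).
#' @export
cohort_universe <- function(spec) {
  sprintf("drug%03d", seq_len(spec$drug_universe_size))
}

#' Generate a synthetic prescription cohort
#'
#' Draws, per subject, a number of admissions in the configured range;
#' each admission receives a background drug set sampled without
#' replacement under Zipf popularity weights. Each planted combination is
#' then unioned into a seeded sample of admissions of at least its target
#' frequency, so [count_combination_frequencies()] is guaranteed to
#' report it at that frequency or higher. Byte-identical output for
#' identical seeds.
#'
#' @param spec a [cohort_spec()].
#' @return List of [admission_drug_set()] objects.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  universe <- cohort_universe(spec)
  zipf_w <- seq_along(universe)^(-spec$zipf_exponent)
  with_seed(spec$seed, {
    sets <- list()
    ids <- list()
    for (s in seq_len(spec$n_subjects)) {
      n_adm <- sample(seq(spec$admissions_per_subject[1L],
                          spec$admissions_per_subject[2L]), 1L)
      for (h in seq_len(n_adm)) {
        sz <- sample(seq(spec$background_set_size[1L],
                         spec$background_set_size[2L]), 1L)
        sz <- min(sz, length(universe))
        drugs <- sample(universe, sz, prob = zipf_w)
        sets[[length(sets) + 1L]] <- drugs
        ids[[length(ids) + 1L]] <- c(sprintf("s%04d", s), sprintf("h%04d", h))
      }
    }
    for (pc in spec$planted_combos) {
      f <- as.integer(pc$frequency)
      if (f > length(sets)) {
        stop("planted frequency ", f, " exceeds the ", length(sets),
             " generated admissions")
      }
      where <- sample.int(length(sets), f)
      for (i in where) sets[[i]] <- union(sets[[i]], pc$drugs)
    }
    mapply(function(id, drugs) {
      admission_drug_set(id[1L], id[2L], drugs, normalize = FALSE)
    }, ids, sets, SIMPLIFY = FALSE)
  })
}

#' Generate a synthetic drug to target-gene map
#'
#' Background drugs draw a gene-set size in `genes_per_drug` and sample
#' genes from a shared pool (so overlaps arise naturally). Each planted
#' block replaces its drug pair's background sets with constructed sets
#' of the requested sizes sharing exactly `overlap` genes; a pair planted
#' in exactly one block therefore has the known Jaccard similarity
#' overlap / (size_a + size_b - overlap). A drug named in several blocks
#' accumulates each block's genes (its background set is dropped on the
#' first plant), so every block's pairwise intersection count stays exact
#' even though the unions, and hence the Jaccard values, grow.
#'
#' @param universe character vector of drug names.
#' @param genes_per_drug integer range (min, max) of genes per drug.
#' @param shared_gene_blocks list of `list(pair = c(a, b), overlap = n,
#'   set_sizes = c(na, nb))` entries; `overlap` may not exceed either set
#'   size.
#' @param gene_pool_size size of the background gene pool.
#' @param seed integer seed.
#' @return A [drug_gene_map()].
#' @export
gen_drug_gene_map <- function(universe, genes_per_drug = c(2L, 8L),
                              shared_gene_blocks = list(),
                              gene_pool_size = 300L, seed = 1L) {
  stopifnot(length(genes_per_drug) == 2L, genes_per_drug[1L] >= 0L,
            genes_per_drug[1L] <= genes_per_drug[2L])
  pool <- sprintf("GENE%04d", seq_len(gene_pool_size))
  with_seed(seed, {
    sets <- lapply(universe, function(d) {
      sz <- sample(seq(genes_per_drug[1L], genes_per_drug[2L]), 1L)
      sz <- min(sz, length(pool))
      if (sz == 0L) character(0) else sample(pool, sz)
    })
    names(sets) <- universe
    planted <- character(0)
    for (i in seq_along(shared_gene_blocks)) {
      blk <- shared_gene_blocks[[i]]
      stopifnot(length(blk$pair) == 2L, length(blk$set_sizes) == 2L)
      if (blk$overlap > min(blk$set_sizes)) {
        stop("planted overlap ", blk$overlap, " exceeds a set size of ",
             min(blk$set_sizes))
      }
      shared <- sprintf("SHARED%02dG%02d", i, seq_len(blk$overlap))
      for (j in 1:2) {
        d <- blk$pair[j]
        own <- sprintf("UNIQ%02dD%dG%02d", i, j,
                       seq_len(blk$set_sizes[j] - blk$overlap))
        base <- if (d %in% planted) sets[[d]] else character(0)
        sets[[d]] <- c(base, shared, own)
        planted <- union(planted, d)
      }
    }
    drug_gene_map(rep(names(sets), lengths(sets)),
                  unlist(sets, use.names = FALSE), normalize = FALSE)
  })
}

#' Risk-label mixture specification
#'
#' Proportions of pair labels drawn by [gen_risk_table()]. The default
#' mixture concentrates mass on Moderate and Unknown, the shape observed
#' in curated interaction databases (roughly 73% Moderate, 20% Unknown,
#' 6% High, with Low and None rare).
#'
#' @param proportions named numeric vector over the five risk levels,
#'   summing to 1.
#' @param seed integer seed.
#' @return Object of class `risk_mix_spec`.
#' @export
risk_mix_spec <- function(proportions = c(High = 1840, Moderate = 21829,
                                          Low = 107, Unknown = 6127,
                                          None = 97) / 30000,
                          seed = 1L) {
  stopifnot(setequal(names(proportions), risk_levels()),
            all(proportions >= 0),
            isTRUE(all.equal(sum(proportions), 1)))
  structure(list(proportions = proportions, seed = as.integer(seed)),
            class = "risk_mix_spec")
}

#' Generate a synthetic drug-pair risk table
#'
#' Samples `n_pairs` distinct unordered drug pairs from the universe
#' (default: all pairs) and assigns each a risk level drawn from the
#' mixture. Empirical label proportions converge to the mixture as the
#' pair count grows; identical seeds give identical tables.
#'
#' @param universe character vector of drug names.
#' @param mix a [risk_mix_spec()].
#' @param n_pairs number of labeled pairs (capped at choose(n, 2)).
#' @return A [risk_table()].
#' @export
gen_risk_table <- function(universe, mix = risk_mix_spec(), n_pairs = NULL) {
  stopifnot(inherits(mix, "risk_mix_spec"))
  if (length(universe) < 2L) return(risk_table())
  all_pairs <- utils::combn(sort_c(universe), 2L)
  total <- ncol(all_pairs)
  if (is.null(n_pairs)) n_pairs <- total
  n_pairs <- min(n_pairs, total)
  with_seed(mix$seed, {
    idx <- sample.int(total, n_pairs)
    levels <- sample(names(mix$proportions), n_pairs, replace = TRUE,
                     prob = mix$proportions)
    risk_table(all_pairs[1L, idx], all_pairs[2L, idx], levels,
               normalize = FALSE)
  })
}

#' Generate a synthetic docking-mode table
#'
#' Emulates ranked docking output: mode 1 is the reference conformation
#' (RMSD 0) and carries the most favorable (most negative) affinity;
#' subsequent modes have weaker affinities, in ascending order, and
#' positive RMSDs. Identical seeds give identical tables.
#'
#' @param n_modes number of poses (>= 1).
#' @param affinity_range numeric (min, max) binding free energy window,
#'   kcal/mol.
#' @param rmsd_range numeric (min, max) RMSD window for non-reference
#'   modes, Angstrom.
#' @param seed integer seed.
#' @return A [docking_modes()] table.
#' @export
gen_docking_modes <- function(n_modes = 9L, affinity_range = c(-12, -5),
                              rmsd_range = c(0, 4), seed = 1L) {
  stopifnot(n_modes >= 1L, affinity_range[1L] <= affinity_range[2L],
            rmsd_range[1L] >= 0, rmsd_range[1L] <= rmsd_range[2L])
  with_seed(seed, {
    aff <- sort(stats::runif(n_modes, affinity_range[1L], affinity_range[2L]))
    rms <- c(0, sort(stats::runif(n_modes - 1L, rmsd_range[1L],
                                  rmsd_range[2L])))
    docking_modes(seq_len(n_modes), aff, rms)
  })
}
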