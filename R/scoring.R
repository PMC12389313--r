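## Docking-derived interaction scoring: RMSD, binding free energy
## arithmetic, per-mode min-max normalization, and the 2/3/4-drug
## composite scores.

#' Root mean square deviation between two conformations
#'
#' sqrt(mean squared per-atom displacement) between a target and a
#' reference coordinate set with corresponding atom order.
#'
#' @param target,reference numeric matrices, one atom per row, 3 columns
#'   (Angstrom). Atom counts and order must correspond.
#' @return RMSD in Angstrom; 0 iff the coordinates are identical.
#' @export
rmsd <- function(target, reference) {
  target <- as.matrix(target)
  reference <- as.matrix(reference)
  if (!all(dim(target) == dim(reference))) {
    stop("coordinate sets differ in shape: ", nrow(target), " vs ",
         nrow(reference), " atoms")
  }
  if (nrow(target) < 1L) stop("coordinate sets must contain at least one atom")
  d <- target - reference
  sqrt(sum(d * d) / nrow(target))
}

#' Binding free energy from end-state components
#'
#' Standard end-state decomposition of the binding free energy:
#' `dG = U_PL - U_P - U_L + W_PL - W_P - W_L - T * dS_config`, with the
#' averaged potential energies U and solvation free energies W of the
#' protein-ligand complex, the isolated protein and the isolated ligand in
#' kcal/mol, the temperature T in Kelvin (default 298), and the
#' configurational entropy change in kcal/(mol K) so the T * dS term is in
#' kcal/mol.
#'
#' @param U_PL,U_P,U_L average potential energies, kcal/mol.
#' @param W_PL,W_P,W_L solvation free energies, kcal/mol.
#' @param dS_config configurational entropy change, kcal/(mol K).
#' @param T_kelvin temperature, K.
#' @return Binding free energy, kcal/mol.
#' @export
#' @examples
#' binding_free_energy(-100, -40, -30, -20, -10, -5)
binding_free_energy <- function(U_PL, U_P, U_L, W_PL, W_P, W_L,
                                dS_config = 0, T_kelvin = 298) {
  stopifnot(T_kelvin > 0)
  U_PL - U_P - U_L + W_PL - W_P - W_L - T_kelvin * dS_config
}

#' Per-mode score weights
#'
#' Affinity is the primary evidence of binding strength, RMSD the
#' auxiliary structural term, so the affinity weight `alpha` must exceed
#' the RMSD weight `beta`; together they partition the unit weight
#' (`alpha + beta = 1`).
#'
#' @param alpha weight of the normalized affinity (default 0.7).
#' @param beta weight of the inverse-normalized RMSD (default 0.3).
#' @return Object of class `mode_score_weights`.
#' @export
mode_score_weights <- function(alpha = 0.7, beta = 0.3) {
  stopifnot(alpha > beta, beta > 0,
            isTRUE(all.equal(alpha + beta, 1)))
  structure(list(alpha = alpha, beta = beta), class = "mode_score_weights")
}

#' Min-max normalize a docking run's affinities and RMSDs
#'
#' Rescales each mode's affinity and RMSD to \[0, 1\] over the run. In the
#' default `"strength"` orientation the mode with the most negative
#' (strongest-binding) affinity gets normalized affinity 1 and the mode
#' with the smallest RMSD gets inverse-normalized RMSD 1, so both terms
#' reward the optimal pose. `orientation = "literal"` instead maps the
#' largest (weakest) affinity to 1. When a run is degenerate (all
#' affinities equal, or all RMSDs equal - e.g. a single-mode run) the
#' normalized value is defined as 1: the sole pose is its own optimum.
#'
#' @param modes a [docking_modes()] table.
#' @param orientation `"strength"` (default) or `"literal"`.
#' @return `data.frame` with columns `mode`, `normalized_affinity`,
#'   `inverse_normalized_rmsd`, sorted by mode index.
#' @export
normalize_modes <- function(modes, orientation = c("strength", "literal")) {
  orientation <- match.arg(orientation)
  if (!inherits(modes, "docking_modes")) {
    modes <- docking_modes(modes$mode, modes$affinity, modes$rmsd)
  }
  a <- modes$affinity
  r <- modes$rmsd
  span_a <- max(a) - min(a)
  span_r <- max(r) - min(r)
  na <- if (span_a == 0) rep(1, length(a)) else switch(
    orientation,
    strength = (max(a) - a) / span_a,
    literal = (a - min(a)) / span_a
  )
  nr <- if (span_r == 0) rep(1, length(r)) else 1 - (r - min(r)) / span_r
  data.frame(mode = modes$mode, normalized_affinity = na,
             inverse_normalized_rmsd = nr)
}

#' Score one docking mode
#'
#' Convex combination of the normalized affinity and inverse-normalized
#' RMSD: `alpha * norm_affinity + beta * inv_norm_rmsd`.
#'
#' @param normalized_affinity,inverse_normalized_rmsd values in \[0, 1\]
#'   from [normalize_modes()].
#' @param weights a [mode_score_weights()].
#' @return Score in \[0, 1\]; vectorized.
#' @export
mode_score <- function(normalized_affinity, inverse_normalized_rmsd,
                       weights = mode_score_weights()) {
  stopifnot(all(normalized_affinity >= 0 & normalized_affinity <= 1),
            all(inverse_normalized_rmsd >= 0 & inverse_normalized_rmsd <= 1))
  weights$alpha * normalized_affinity + weights$beta * inverse_normalized_rmsd
}

#' Score a drug from its own docking run
#'
#' The drug's individual score is the mode-1 (optimal pose) score after
#' min-max normalization over the run.
#'
#' @param modes a [docking_modes()] table.
#' @param weights a [mode_score_weights()].
#' @param orientation passed to [normalize_modes()].
#' @return Score in \[0, 1\].
#' @export
drug_score <- function(modes, weights = mode_score_weights(),
                       orientation = "strength") {
  norm <- normalize_modes(modes, orientation)
  i <- which(norm$mode == 1L)
  mode_score(norm$normalized_affinity[i], norm$inverse_normalized_rmsd[i],
             weights)
}

#' Overall score of a drug pair from individual scores
#'
#' Arithmetic mean of the two drugs' individual scores.
#'
#' @param s1,s2 individual drug scores in \[0, 1\].
#' @return Mean score in \[0, 1\].
#' @export
pair_overall_score <- function(s1, s2) {
  stopifnot(all(s1 >= 0 & s1 <= 1), all(s2 >= 0 & s2 <= 1))
  (s1 + s2) / 2
}

#' Interaction score of a drug pair from its pairwise docking run
#'
#' Realized as the mode-1 score of the pair's own docking run (min-max
#' normalization followed by the weighted mode score).
#'
#' @param modes_pair [docking_modes()] from docking the two drugs
#'   together.
#' @param weights a [mode_score_weights()].
#' @param orientation passed to [normalize_modes()].
#' @return Score in \[0, 1\].
#' @export
pair_interaction_score <- function(modes_pair,
                                   weights = mode_score_weights(),
                                   orientation = "strength") {
  if (is.null(modes_pair) || NROW(modes_pair) == 0L) {
    stop("empty docking run: no modes to score")
  }
  drug_score(modes_pair, weights, orientation)
}

#' Composite mixing weight
#'
#' Mixes the average individual score with the average pairwise
#' interaction score in the 3- and 4-drug composites; the recommended
#' default is 0.5.
#'
#' @param gamma mixing weight in \[0, 1\].
#' @return Object of class `composite_mix`.
#' @export
composite_mix <- function(gamma = 0.5) {
  stopifnot(gamma >= 0, gamma <= 1)
  structure(list(gamma = gamma), class = "composite_mix")
}

composite_score <- function(individual, pairwise, mix) {
  stopifnot(all(individual >= 0 & individual <= 1),
            all(pairwise >= 0 & pairwise <= 1))
  mix$gamma * mean(individual) + (1 - mix$gamma) * mean(pairwise)
}

#' Composite overall score for a 3-drug combination
#'
#' `gamma * mean(individual scores) + (1 - gamma) * mean(pairwise
#' interaction scores)`: with `gamma = 1` the composite collapses to the
#' individual mean, with `gamma = 0` to the pairwise mean. Invariant under
#' relabeling of the drugs.
#'
#' @param individual numeric length 3: the drugs' individual scores
#'   (S_A, S_B, S_C).
#' @param pairwise numeric length 3: the pairwise interaction scores
#'   (I_AB, I_AC, I_BC).
#' @param mix a [composite_mix()].
#' @return Composite score in \[0, 1\].
#' @export
triple_overall_score <- function(individual, pairwise,
                                 mix = composite_mix()) {
  stopifnot(length(individual) == 3L, length(pairwise) == 3L)
  composite_score(individual, pairwise, mix)
}

#' Composite overall score for a 4-drug combination
#'
#' Same mixing rule as [triple_overall_score()] over the 4 individual
#' scores and the 6 pairwise interaction scores.
#'
#' @param individual numeric length 4.
#' @param pairwise numeric length 6 (the AB, AC, AD, BC, BD, CD scores).
#' @param mix a [composite_mix()].
#' @return Composite score in \[0, 1\].
#' @export
quad_overall_score <- function(individual, pairwise,
                               mix = composite_mix()) {
  stopifnot(length(individual) == 4L, length(pairwise) == 6L)
  composite_score(individual, pairwise, mix)
}
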