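---
title: "Methods: mining, risk scoring and greedy substitution of drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, risk scoring and greedy substitution of drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grdc)
```

## The problem

Patients with multi-organ autoimmune disease (systemic lupus
erythematosus, antiphospholipid syndrome) routinely receive many drugs per
hospitalization. Which co-prescriptions are common, which carry
interaction risk, and — when a combination contains a risky drug — what is
a safer, mechanistically similar substitute? `grdc` answers these three
questions with a pipeline of small, composable stages, each of which can
also be used alone.

## Mining frequent combinations

The counting unit is the **admission**: one hospitalization's de-duplicated,
name-normalized drug set. Normalization (`normalize_drug_name()`)
lowercases, removes bracketed content — round, square or curly brackets,
nested groups removed outside-in — deletes every character outside
`[a-z0-9 -]`, collapses whitespace and trims; it is idempotent, and a name
that becomes empty is rejected rather than silently kept. Multi-ingredient
names ("sodium chloride 09") stay single tokens: there is no reliable
delimiter between ingredient and strength in free-text EHR fields.

Each admission is expanded into all drug subsets of size 1 to 4
(`enumerate_combinations()`), so an admission with $n$ drugs contributes
$\sum_{k=1}^{4}\binom{n}{k}$ canonical tuples, each counted **at most once
per admission**. Size-1 "combinations" are retained deliberately: they
carry the single-drug mass that downstream labeling marks `None`, and they
define the candidate universe of the recommender. A `per_subject` switch
collapses a subject's admissions to their union set for sensitivity
analyses; the default keeps the admission as the unit because repeat
hospitalizations are independent prescribing decisions.

`select_high_frequency()` applies the frequency floor (default 4
admissions) **before** the top-$n$ cap (default 30,000): the cap is meant
to trim an already-qualified ranked list, not to substitute for the
floor. Ties at any rank are broken lexicographically on the canonical
key, using a radix (C-locale) sort, so the output is a pure function of
the counter regardless of input order or session locale.

## Docking-derived interaction scores

For drugs and drug pairs with docking output (mode index, binding
affinity in kcal/mol, RMSD in Å), each run is min–max normalized and the
optimal pose (mode 1) is scored as

$$\mathrm{Score} = \alpha \cdot \mathrm{NormAffinity} + \beta \cdot
\mathrm{InvNormRMSD}, \qquad \alpha > \beta,\ \alpha + \beta = 1 .$$

Two numerical choices matter:

* **Orientation.** The default (`orientation = "strength"`) maps the most
  negative — strongest-binding — affinity to 1, because lower free energy
  means stronger, more stable binding and the score must reward binding
  strength for the downstream risk ranking to be coherent. A literal
  min-to-0/max-to-1 rescale is available behind
  `orientation = "literal"` for comparison.
* **Degenerate runs.** When a run has a single mode, or all affinities
  (or RMSDs) are equal, the normalized value is defined as 1: the sole
  pose is its own optimum. This avoids division by zero and makes the
  single-mode case testable rather than undefined.

The weights default to $\alpha = 0.7$, $\beta = 0.3$ — the only hard
constraints are $\beta < \alpha$ (affinity is the primary evidence, RMSD
auxiliary) and that they partition unit weight; both are configurable.
Pair scores average the two drugs' individual scores; a pair's own
docking run, when available, is scored the same way
(`pair_interaction_score()`), and the package falls back to the
individual-score mean when no pairwise run exists. Composites for 3 and 4
drugs mix the individual mean with the pairwise mean,

$$\mathrm{Overall} = \gamma \cdot \overline{S}_{\mathrm{indiv}} +
(1-\gamma)\cdot \overline{I}_{\mathrm{pair}}, \qquad \gamma = 0.5
\text{ by default},$$

so $\gamma = 1$ recovers the individual mean and $\gamma = 0$ the
pairwise mean — both limits are asserted in the test suite. The helper
`binding_free_energy()` implements the end-state decomposition
$\Delta G^\circ = U_{PL} - U_P - U_L + W_{PL} - W_P - W_L -
T\,\Delta S_{\mathrm{config}}$ with $T = 298\,$K by default and
$\Delta S_{\mathrm{config}}$ in kcal/(mol·K), so the entropy block is in
kcal/mol; running the underlying simulations is out of scope — the
arithmetic consumes their outputs.

## Risk labels

Scores map to classes with closed lower boundaries: High at
$\ge 0.75$, Moderate at $\ge 0.5$, Low below — a partition of $[0,1]$
with no gaps. Combination labels take the **maximum severity** over the
combination's pairs under the total order High > Moderate > Low >
Unknown > None. Two design points:

* `None` sits below `Unknown` and is reserved for single-drug
  combinations, which have no pairs to assess; `Unknown` is the label for
  a pair absent from the curated table. Keeping them distinct preserves
  the information that a pair was *looked up and not found* versus *never
  a pair at all*.
* When both a curated risk table and computed scores are available, the
  curated table wins: database severities are human-reviewed, docking
  scores are a model. The score-based path is the fallback
  (`label_combinations(combos, risks = NULL)` classifies a `score`
  column).

## The drug–gene network

The network is bipartite by construction: drug nodes keyed
`"name_RiskLevel"` — the same drug appears as distinct nodes under
distinct risks, which is the point of the encoding — and one shared node
per gene symbol. Colors are fixed constants (High red, Moderate orange,
Low gold, Unknown gray, None white, genes green); where sources disagree
between "gold" and "yellow" for Low we use gold. Edges copy their drug
node's risk so edge-colored renderings are possible downstream;
`network_stats()` reports both raw drug-node counts and
distinct-underlying-drug counts since summaries of such networks are
ambiguous between the two. Export is GraphML via igraph; layout and
rendering are out of scope.

## Greedy recommendation and substitution

A candidate $c$ against input combination $D$ scores

$$\mathrm{Total}(c) = \alpha \sum_{\substack{S \subseteq D \\ 1 \le |S|
\le 2}} \mathrm{freq}(S \cup \{c\}) \;+\; \beta \sum_{d \in D}
|G_c \cap G_d| \;+\; \gamma \sum_{d \in D} \mathrm{penalty}(c, d)$$

with defaults $\alpha = 1.0$, $\beta = 2.0$, $\gamma = 1.0$ and penalties
High $-10$, Moderate $-5$, Low $-1$, Unknown/None $0$. The frequency term
reads "2–3-tuples formed with the input drugs" as $S \cup \{c\}$ for
non-empty subsets $S$ of at most two input drugs — the minimal reading
consistent with accumulating 2- and 3-tuple counts. Unknown pairs are
deliberately unpenalized: punishing missing data would conflate "not
assessed" with "safe enough to assess and rank Low". Raw counts, not
normalized frequencies, enter the total: the scoring formula takes the
frequency itself, and min–max normalization of the *totals* already
absorbs scale. The printed 0–100 score is that min–max rescale over the
scored pool, rounded half-up (printed scores are integers); a
single-candidate or all-tied pool scores 100. All ranking ties break
lexicographically for determinism.

Substitution (`recommend_substitute()`) scores candidates against the
context $D \setminus \{r\}$ after removing the risky drug $r$, and admits
only candidates whose own label against that context (maximum pair
severity) does not exceed $r$'s — a substitute never raises the risk
class. The 0–100 normalization runs over this admissible pool, i.e. the
candidates actually returned. Jaccard similarity
$|G_a \cap G_b| / |G_a \cup G_b|$ between substitute and replaced drug
(0 when both sets are empty) is attached as the mechanistic-similarity
proxy; it ignores directionality (agonist vs antagonist), expression and
pathway context, and is reported, not used as a filter. One drug is
substituted at a time; joint multi-drug substitution is a non-goal.

## Evaluation harness

No public ground truth defines "the right recommendation", so the harness
manufactures one: a seeded shuffle splits admissions 80/20; the counter
is trained on the 80%; each test admission with $\ge 2$ drugs has one
drug held out — the lexicographically last by default, a seeded draw with
`holdout = "random"` — and the recommender must recover it from the rest.
Precision@k, Recall@k, F1@k and Hit@k are averaged over cases on the 0–1
scale (the CLI prints percent). Under these standard definitions
per-case precision@k $\le$ hit@k always holds — with a single held-out
drug, precision@10 can never exceed hit@10/10 — so absolute values on
this protocol are not comparable to evaluations with richer relevance
sets; the harness is for controlled comparisons (weights, mining
thresholds, holdout policy) under identical seeds.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage has a recoverable planted truth:

* `gen_cohort()` draws background drug sets under a Zipf popularity law
  (default exponent 1.5, 100 subjects, 1–3 admissions each, 3–10
  background drugs per admission over a 60-drug universe), which
  reproduces the heavy-tailed, decaying rank-frequency curve of real
  co-prescription corpora; planted combinations are unioned into a seeded
  sample of admissions so their mined frequency is at least the target.
* `gen_drug_gene_map()` gives each drug 2–8 genes from a 300-gene pool;
  planted blocks construct pair sets with exact intersection counts (a
  drug in several blocks accumulates each block's genes, keeping every
  intersection count exact while unions grow).
* `gen_risk_table()` draws pair labels from a mixture defaulting to
  roughly 73% Moderate, 20% Unknown, 6% High, with Low and None rare —
  the shape of curated interaction databases.
* `gen_docking_modes()` emits ranked poses with mode 1 as the reference
  (RMSD 0, best affinity), affinities in $[-12, -5]$ kcal/mol and RMSDs
  up to 4 Å.

All randomness flows from explicit seeds through a private RNG stream;
the caller's `.Random.seed` is untouched. What the generators do **not**
emulate: real pharmacology (no therapeutic classes, no dosing), drug-name
messiness beyond what the normalizer handles, correlation between a
pair's interaction severity and its co-prescription frequency, or the
MIMIC schema beyond the three consumed columns. Passing tests therefore
demonstrate algorithmic correctness and parameter recovery under the
stated statistical shape — not clinical validity of any recommendation.

## Problem sizes and determinism

The test suite and the acceptance script run on corpora of tens to a few
hundred admissions over universes of up to 60 drugs, with brute-force
oracle comparisons on instances of at most 8 admissions × 8 drugs
(several hundred seeded trials) — sizes chosen so exhaustive enumeration
remains a feasible independent check of the production path. Every
sort is radix-based and every tie-break lexicographic, so identical
inputs give byte-identical outputs across platforms and locales.

## Known limitations

* Frequency, overlap and penalty live on different natural scales; the
  default weights embody one empirically tuned trade-off, and the min–max
  normalization hides scale, not imbalance. Re-tune weights per corpus.
* The curated-table-first precedence for labels means a stale table
  silently overrides fresher docking evidence.
* Gene-set Jaccard treats all targets equally; two drugs sharing one
  promiscuous target can look as similar as two sharing a specific one.
* The evaluation protocol's single held-out drug caps precision@k at
  1/k; its value is relative comparison, not headline numbers.
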