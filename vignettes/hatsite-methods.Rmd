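---
title: "Predicting HAT-specific lysine acetylation sites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HAT-specific lysine acetylation sites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatsite)
```

## The problem

Thousands of lysine acetylation sites are known from proteomics, but for most
of them the upstream enzyme — the histone/lysine acetyltransferase (HAT) —
is unknown. `hatsite` predicts, from sequence alone, which of seven
well-characterized HATs (CREBBP, EP300, HAT1, KAT2A, KAT2B, KAT5, KAT8) is a
plausible writer of a given lysine. The premise is the classic one of
group-based prediction: short peptides with similar sequences tend to have
similar biochemistry, so a lysine whose flanking peptide resembles the known
substrate peptides of a HAT is a candidate substrate of that HAT.

## Scoring model

An *acetylation site peptide* ASP($m$, $n$) is the central lysine plus $m$
upstream and $n$ downstream residues; positions beyond a terminus are padded
with `*`, which scores 0 against everything (as does the unknown residue
`X`). Two equal-length peptides $A$ and $B$ are compared with a substitution
matrix:

$$S(A,B) = \sum_i \mathrm{Score}(A[i], B[i]), \qquad
  S'(A,B) = \sum_i w_i\,\mathrm{Score}(A[i], B[i]),$$

with $S$ (or $S'$) redefined as 0 whenever the sum is negative; the clamp is
applied to the **sum**, not per position. $w_i \ge 0$ are integer position
weights. The model score of a query window is the arithmetic mean of
$S'$ against every known substrate peptide of the HAT. The matrix starts as
BLOSUM62; rows are indexed by the query residue and columns by the reference
residue, so a mutated matrix may be asymmetric.

## Training

Performance is monitored throughout by leave-one-out (LOO) validation:
every positive is scored with itself withheld from the reference set
(withholding is by origin — protein and position — so identical peptides
from different proteins are kept), negatives are scored against all
positives. The training objective is LOO sensitivity ($Sn$) at a fixed
specificity ($Sp$) anchor of 90%. The anchored cutoff is placed just above
the $\lceil 0.9\,n_\text{neg}\rceil$-th smallest negative score, so
negatives tied with that score fall below the cutoff and the achieved $Sp$
is always $\ge$ the anchor.

Training has three steps, run in a configurable order (default as listed):

1. **Motif length selection.** All $(m, n)$ combinations in the configured
   ranges are evaluated exhaustively with unit weights and unmutated
   BLOSUM62; ties are broken toward the smaller $m + n$, then the smaller
   $m$. A prefix-sum kernel scores all sub-windows of the maximal window in
   one pass.
2. **Weight training.** A random position's integer weight is changed by
   $\pm 1$; improvements are always adopted. A $-1$ on a zero weight is
   rejected outright, keeping weights non-negative.
3. **Matrix mutation.** A random ordered residue pair of the $20 \times 20$
   block is changed by $\pm 1$; padding and `X` entries are never touched.

Steps 2–3 use simulated annealing: a worsening move is accepted with
probability $\exp(\Delta Sn / T)$, $T_0 = 0.05$, geometric cooling factor
$0.995$ per proposal. Because an objective-neutral move is accepted with
probability 1, a step whose stopping rule counted only *rejected* proposals
could cycle forever on a flat objective; a step therefore stops after
`max_stagnation` consecutive proposals that fail to improve the
**best-so-far** objective (default 500), or after `max_proposals` in total
(default 10,000). The returned state is the best-so-far, never a worse
final annealing state, so the best-objective column of the training trace
is monotone non-decreasing — a property the test suite asserts on every
run. All randomness flows from a single integer seed; identical seed and
configuration replay bit-identically.

After training, the **High / Medium / Low** thresholds are calibrated from
the LOO score distribution as the smallest observed score whose LOO
specificity reaches ~95% / 90% / 85%; the **All** tier reports every lysine
with its score. Prediction uses the inclusive rule (site reported when
score $\ge$ cutoff).

## Evaluation

$Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Pr = TP/(TP+FP)$; a $0/0$ ratio is
reported as missing rather than 0. ROC curves place one vertex per distinct
score (tied scores move the curve diagonally) and the trapezoidal AUC is
therefore exactly the Mann–Whitney statistic with half credit for ties —
verified against a brute-force pairwise oracle. Stratified $k$-fold
cross-validation splits positives and negatives independently so folds
preserve class balance; by default each fold is scored against the other
folds' positives with the trained weights and matrix kept fixed
(re-partitioning the reference set only), because the reference-set
partition is what LOO itself varies; `retrain = TRUE` additionally re-runs
the stochastic steps per fold. $k$ may not exceed the number of positives
(the smallest HATs support only small $k$, which is why 4- and 6-fold are
the natural choices there).

## Synthetic benchmark data

The generator emulates the annotation-table-plus-sequences shape of real
substrate data: i.i.d. background residues (uniform over the 20 amino acids
by default; a database-average composition is also provided), planted
central lysines, and informative offsets enriched for a fixed residue with
probability 0.9 (`clean`) or 0.4 (`weak`). Presets mirror observed motif
patterns: G at −1 / S at +1 / K at +3..+5 (CREBBP-like), A at −1 / K at +1 /
K at +3..+5 (EP300-like), G at −2 and −4 (KAT2B-like), and a null preset
with no signal. Planted sites keep ≥ 61 residues apart (the maximal
ASP(30, 30) width) and ≥ 30 residues from the termini so positive windows
never overlap; background lysines serve as natural negatives. What passing
tests on these data show is that the pipeline recovers planted,
position-specific, single-residue enrichments over an i.i.d. background;
real substrates have compositional bias, correlated positions, domain
structure and annotation noise that the generator deliberately does not
model, so synthetic performance is an upper bound on real-data behavior.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sp_anchor` | 0.90 | specificity fixed while comparing $Sn$ during training |
| `m_range`, `n_range` | 1..30 | candidate upstream/downstream half-widths |
| `max_stagnation` | 500 | proposals without a new best before a step stops |
| `max_proposals` | 10,000 | hard cap per stochastic step |
| `sa_T0`, `sa_cooling` | 0.05, 0.995 | annealing temperature and cooling |
| `step_order` | length, weights, matrix | order of the three steps |
| thresholds | $Sp \approx$ 0.95/0.90/0.85 | High / Medium / Low calibration |

The benchmark and test runs in this package use a reduced problem size —
windows searched up to ASP(8, 8), `max_stagnation = 120`,
`max_proposals = 400`, studies of 60 substrates × 3 sites (~360 residues
each) — which keeps a full train-and-validate cycle under two seconds while
covering every informative offset of the presets with room to spare.

## Numerical and degenerate-case choices

* Clamping to zero happens on the weighted sum, before averaging over
  reference peptides.
* The anchored cutoff resolves score ties by placing the cutoff above the
  tied block, so the anchored specificity is never silently undershot.
* Calibration cutoffs are chosen among observed scores; when all negatives
  tie (e.g. all score 0), the three tiers coincide at the smallest positive
  score.
* Training refuses datasets with fewer than two positives rather than
  degrading silently; LOO scoring refuses a reference set that would be
  empty after exclusion.
* A lysine annotated for a different HAT counts as a negative for the HAT
  being trained — per-HAT annotation is the only label available, and the
  convention matches taking "all other lysines in the same proteins" as
  negatives.

## Known limitations

* When the anchored objective is already 1.0 (fully separable data — the
  usual case on clean synthetic studies), improvement-driven weight and
  matrix moves can never be adopted, and trained weights remain the initial
  unit vector. Position weights differentiate only on partially separable
  data; the test suite demonstrates recovery of informative offsets on
  weak-enrichment studies.
* The anchored-sensitivity objective is a step function of the scores, so
  annealing plateaus are common; the stagnation rule, not convergence in
  objective, is the practical stopping criterion.
* Orthology screening consumes precomputed similarity-search hit tables;
  it does not run the search itself, and applies no e-value ceiling unless
  one is requested.
* Large-scale acetylome annotation restricts scoring to the listed sites by
  design; scanning whole proteomes at permissive tiers produces an
  impractical false-positive load.

## A worked micro-example

```{r example}
spec <- make_motif_spec("crebbp-like")
study <- sample_study(spec, n_substrates = 20, seed = 1)
cfg <- train_config(m_range = 1:6, n_range = 1:6,
                    max_stagnation = 60, max_proposals = 200, seed = 1)
model <- train_model(study$substrates, study$annotations, "CREBBP", cfg)
model
report <- loo_validate(study$substrates, study$annotations, "CREBBP", model)
report
```

The trained window covers the informative offsets, the LOO AUC is near 1 on
this clean benchmark, and the calibrated tiers sit at their target
specificities.
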