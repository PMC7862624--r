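---
title: "The flexible scoring card method: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flexible scoring card method: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscm)
```

## The model

The scoring card method is a linear, fully interpretable classifier for
labeled peptide sets. Its parameters are a *scorecard*: one propensity
score per symbol — 400 dipeptides, or 20 amino acids — on a common
0–1000 scale, plus a single decision threshold.

**Initial scorecard.** For a region-sliced training set, pool the symbol
counts of each class and normalize by the class totals, giving the
class compositions `NPS+` and `NPS−`. The raw propensity of symbol *i*
is the difference `NPS+_i − NPS−_i`: positive where the symbol is
enriched in the positive class. The raw vector is min–max scaled so the
most negative-associated symbol scores 0 and the most
positive-associated scores 1000. With pooled counts 280/450 in the
positive class and 40/200 in the negative class, a dipeptide's
compositions are 0.622 and 0.2 and its raw propensity is 0.422:

```{r worked}
cc <- worked_example_composition()
c(nps_pos = unname(round(cc$nps_pos["KK"], 3)),
  nps_neg = unname(cc$nps_neg["KK"]),
  raw = unname(round(initial_propensity(cc)["KK"], 3)))
```

The subtraction direction matters: higher scores must mean "more
positive-class-like" for the downstream interpretation (top-ranked
dipeptides characterize activity) to hold, and the worked numbers above
are only consistent with `NPS+ − NPS−`.

**Scoring and classification.** A peptide **P** is scored by
`S(P) = Σ x_i · PS_i` with `x_i` its *normalized* composition on the
card's region. Because the weights sum to one, `S(P)` is a weighted mean
of card scores: it stays on the 0–1000 scale for a 5-mer and a 30-mer
alike, which is what makes one global threshold meaningful. A raw-count
weighting (`weighting = "count"`) is available for comparison but scales
with length. Classification is strict: positive iff
`S(P) > threshold`; ties go negative.

**Regions.** Eleven scorecard flavours differ only in the slice of
sequence that composition is computed on: the whole sequence
(amino-acid `APS` or dipeptide `DPS` granularity) or the first/last
5/10/15 residues and their N+C concatenations. Sequences shorter than a
terminal window are used whole rather than dropped — benchmark sets
contain 5-mers, and no minimum length beyond the two residues a
dipeptide needs is imposed. For concatenated N+C regions the pair
straddling the junction does not occur in the peptide itself; it is
counted by default (the simplest reading of "join the termini and take
dipeptide composition") with `junction = "exclude"` exposing the other
convention, since neither can be ruled out a priori.

**Per-residue propensities.** A dipeptide card is reduced to 20 residue
propensities by averaging, for residue r, the 40 dipeptide scores
containing r (20 pairs rX and 20 pairs Xr; the doubled pair rr counts
twice). These 20 values are what get correlated with physicochemical
scales.

## Genetic-algorithm refinement

The initial card is a sound statistic but not optimal for
classification. A real-valued GA perturbs the full score vector under
the fitness

`F = w1 · AUC + w2 · R`, defaults `w1 = 0.9`, `w2 = 0.1`,

where AUC is the area under the ROC curve of the weighted-sum scores on
the training set and R is the Pearson correlation between the candidate
and the initial card. The correlation term is the method's
interpretability anchor: it penalizes refined cards that abandon the
statistical structure of the initial one. With `w2 = 1, w1 = 0` the
optimum is the initial card itself, a property the test suite checks.

The GA scheme (all knobs in `ga_config()`): individuals are full score
vectors initialized as the initial card plus Gaussian noise with one
exact copy preserved; tournament selection (size 3); uniform crossover
(rate 0.8); per-gene Gaussian mutation (rate 0.05, sigma 50 on the
0–1000 scale); elitism (1); clipping to [0, 1000] after every
generation, which keeps candidate and initial cards on one scale so R is
well-behaved; population 100 × 50 generations. Elitism makes the best
fitness trace non-decreasing, so refinement can never end worse than it
started. The threshold is not part of the chromosome; it is fitted post
hoc on the training scores of the best individual.

**Fitness AUC.** The default computes a stratified tenfold
cross-validated AUC — the fold partition assesses ranking stability of
the fixed candidate scores; nothing is refit per fold, because a
scorecard has no per-fold parameters. `auc_method = "full"` uses the
single full-training-set AUC, which is markedly faster and is what the
packaged long-running checks use (problem sizes: 320 training peptides,
population 100, 50 generations, about 5 s per run). Both are exposed
because the choice trades fidelity of the fitness signal against
runtime, not correctness.

**Determinism.** One master seed derives the fold assignment, the GA
initialization and, in `multirun_optimize()`, the per-run seeds
(`seed + run index`); two runs with the same configuration are
bit-identical.

## Threshold selection

No published rule exists for the threshold, only its values. The package
maximizes training accuracy over a candidate grid: the midpoints of
adjacent sorted unique scores, plus one cutoff below the minimum and the
maximum score itself. The two boundary candidates realize the
all-positive and all-negative rules, guaranteeing the selected cutoff is
never worse than the majority rule even on adversarial score patterns —
a guarantee midpoints alone cannot give. Accuracy ties break toward the
lower cutoff, favouring sensitivity.

## Evaluation

`confusion_metrics()` implements the universal binary definitions
(Ac, Sn, Sp, MCC with the zero-denominator convention MCC = 0);
`roc_auc()` computes the Mann–Whitney AUC via midranks (ties get half
credit) and traces the ROC by a descending-score sweep whose trapezoidal
area equals the rank statistic to 1e−9. Both are verified against
brute-force oracles (exhaustive pairwise counting; closed-form MCC) and
the AUC additionally against pROC. Peptides whose region slice is
shorter than one dipeptide are reported as unscorable, never silently
dropped.

## Physicochemical characterization

Residue propensities are correlated (Pearson, on property *values*, not
display ranks) with AAindex-style 20-value scales; records with missing
entries are excluded before correlation, and scales with
|R| strictly greater than 0.5 are flagged informative. The package
bundles a published 20-residue reference card and its three informative
scales (amphiphilicity MITS020101, helix weight QIAN880113,
hydrophobicity JOND750101) so the workflow is testable offline. Of the
three printed correlations, 0.577 and 0.569 reproduce exactly from the
printed columns; the third prints 0.541 but recomputes to 0.451 from its
own table — an inconsistency in the source table that the package
surfaces rather than hides (`reference_correlations_printed()` stores the
printed values for provenance; computed results report 0.451, which
falls below the 0.5 selection cutoff).

## The synthetic generator: what it does and does not show

`generate_peptides()` draws negatives residue-by-residue from a
background distribution (uniform by default) and positives from a
first-order Markov chain whose transition weight into pair ab is
multiplied by `effect_size` for enriched pairs. The signal unit is the
dipeptide — exactly the feature the scorecard measures — so recovery
tests probe the scorecard arithmetic directly rather than the
generator's cleverness. Defaults: 200 peptides per class, lengths 10–30,
KK/LW/GH enriched five-fold, seed 7. Per-sequence sub-seeds are derived
by hashing (master seed, class, counter), so a dataset is stable under
subsetting and different master seeds give unrelated streams.

At those defaults the planted dipeptides reliably land in the top decile
of initial scores (typically the top 3 of 400), and held-out AUC rises
monotonically with effect size. But the *classification accuracy*
achievable is modest: a five-fold tilt on three of 400 pairs leaves most
positives containing no planted pair at all (measured: 44% of positives
carry at least one, versus 10% of negatives), so even the Bayes-optimal
rule sits near 0.7 accuracy and the initial card reaches about 0.59.
Score-ranking recovery and accuracy are different questions at this
effect size, and the tests assert what the conditions support. Real
benchmark peptides differ in length distribution, residue background,
class redundancy structure and the diffuseness of the signal; passing
these tests shows the estimator recovers pair-level enrichment it is
pointed at, not that any particular accuracy transfers to real data.

The no-signal configuration (`effect_size = 1`) makes the classes
exchangeable; across 20 seeds the mean tenfold cross-validated AUC of
per-fold initial cards is 0.5 within ±0.07 (per-seed values at n = 400
scatter with sd ≈ 0.04, so the band is a statement about the mean, not
every seed).

## Numerical choices and degenerate inputs

- Min–max normalization divides before scaling (`(x−min)/(max−min)·1000`)
  so both endpoints are hit exactly; a constant raw vector maps to the
  direction-neutral midpoint 500 instead of erroring, keeping degenerate
  folds alive.
- Dipeptides absent from both classes get raw score 0 and are scaled
  like any other entry; no pseudocounts.
- A constant candidate inside the GA has undefined correlation; R is
  taken as 0 with a warning. The standalone `pearson()` used for
  property analysis errors instead — a constant scale is a data problem
  the user should see.
- Scorecard TSVs round-trip at full precision; the parser reads the
  symbol column with missing-value handling disabled because "NA" is the
  Asn–Ala dipeptide.
- Scores are clipped, not reflected, at the scale boundaries after
  mutation.

## Known limitations

- The GA is a documented standard scheme, not a reimplementation of any
  particular published configuration; refined cards should be compared
  by the reported fitness/AUC, not expected to match external score
  tables entry-wise.
- Cross-validation of a scorecard assesses ranking stability of global
  scores; it is not model selection, and the "folds" do not refit
  anything in the default fitness.
- The method is position-agnostic within a region: two peptides with
  equal region composition are indistinguishable regardless of residue
  order beyond adjacent pairs.
- Only the 20 canonical residues are supported; records with extended
  codes are skipped (loading) or rejected (prediction) by policy.
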