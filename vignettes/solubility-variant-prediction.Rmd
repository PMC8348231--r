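---
title: "Predicting solubility effects of amino acid substitutions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting solubility effects of amino acid substitutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvar)
```

# The problem and the model

A single amino acid substitution can decrease a protein's solubility,
increase it, or leave it unchanged. `solvar` predicts which of the three,
from sequence alone — no structure, no homology search. Three-class
solubility corpora are heavily imbalanced (roughly half of curated cases
decrease solubility, a sixth increase it), which shapes two of the package's
central choices: a cascade architecture that isolates the dominant class
first, and an evaluation layer that re-weights classes before comparing
methods.

## Feature space

Each variant (protein sequence, 1-based position, wild-type residue wt,
mutant residue mut) maps to a named numeric vector with four blocks:

* **AAindex deltas** — one feature per amino acid property scale, encoded as
  `value(mut) − value(wt)`. The encoding is one of several defensible
  substitution-level encodings of a 20-value scale (deltas, wt/mut value
  pairs, or both); the package uses the delta form because it yields one
  antisymmetric scalar per scale (`slice(A→V) = −slice(V→A)`), and records
  the convention here rather than in the feature names. Every scale with 20
  complete values in the supplied AAindex1 file is used; scales with missing
  values are dropped at parse time, since no delta can be formed from an
  incomplete scale.
* **Variation type** — a 20 × 20 one-hot over ordered (wt, mut) cells plus a
  6 × 6 one-hot over residue-group cells (hydrophobic V/I/L/F/M/W/Y/C,
  negative D/E, positive R/K/H, conformational G/P, polar N/Q/S, other A/T),
  436 indicators in total. Diagonal group cells are legal (within-group
  substitutions); diagonal residue cells are not (a substitution must change
  the residue).
* **Neighborhood window** — counts over the 23 positions centered on the
  site (11 each side; the center contributes its wild-type residue): 20
  per-residue counts `AA20D.*` and five class summaries (`NonPolarAA`,
  `PolarAA`, `ChargedAA`, `PosAA`, `NegAA`). The polarity/charge partition
  (nonpolar A/V/L/I/P/F/M/W/G; polar S/T/C/Y/N/Q; positive K/R/H; negative
  D/E) is the standard biochemical one; it is passed as an argument to
  `neighborhood_counts()`, so an alternative partition is a one-line change.
  `ChargedAA = PosAA + NegAA` by construction. At sequence ends the window
  is truncated, never padded: padding would fabricate residues, and
  truncated counts remain interpretable (position 1 sees 12 residues).
* **Protein type** — the sequence length, the single global feature.

Conservation features (a SIFT score and a homolog count) exist in this
problem's lineage but require network homology searches; the package
declares them as an optional all-missing stub (`conservation = TRUE`),
excluded by default, and no shipped feature set uses them.

Only the 20 canonical residues are accepted anywhere; B/J/O/U/X/Z are
rejected at parse time with the offending position named, because every
feature table is defined over the 20-letter alphabet and imputation would be
silent guesswork.

## Classifiers

Both architectures use gradient-boosted decision-tree ensembles (xgboost
backend; gradient boosting over decision trees is the model class of choice
here, and alternative boosters behave near-identically on this problem).
Defaults: 100 boosting rounds, learning rate 0.1, maximum depth 6, no
row/column subsampling, one thread. The no-subsampling default is
deliberate: fits are then bit-for-bit reproducible given (data, parameters,
seed), which the test suite asserts. No class re-weighting is applied during
fitting — imbalance is handled in the assessment layer instead, so the
fitted scores remain calibrated to the training distribution.

The **two-layer cascade** trains layer 1 (decrease vs not-decrease) on all
cases and layer 2 (increase vs no-effect) on the non-decreasing cases only.
At prediction, a case whose layer-1 score reaches the decision threshold is
called `decrease` and layer 2 is never consulted for it; ties go to the
positive class (score ≥ threshold). The threshold defaults to 0.5 on both
layers and is a plain argument. The six features shared by the default layer
sets are fitted independently in each layer. The **single-layer**
alternative is one three-class softprob model; its conventional feature
budget is 30 features against the cascade's 20 + 20.

## Recursive feature elimination

`rfe_select()` fits on the current set, ranks by gain importance, drops the
`step` least-important features and repeats until `target_k` remain. The
strict form drops one feature per iteration (`step = 1`); larger steps are a
speed knob. Two numerical details matter: features never used in any split
receive importance exactly 0 (they are reported, not dropped from the
ranking); and ties — typically among zero-importance features — are broken
deterministically by dropping the feature latest in column order first, so
the elimination order is a reproducible permutation of the feature space.

# Validation protocol

Curated solubility corpora contain deep mutational scans with many
substitutions at one position. Random splitting would let a model see a
position in training and be tested on its neighbors' labels at the same
position. All partitioning here is therefore **group-atomic by (protein,
position)**: `grouped_split()` assigns whole groups to sides, `make_folds()`
deals whole groups to folds, and `run_blind_test()` refuses to run if any
group leaks across the boundary. Group atomicity is extended from the blind
split to cross-validation folds as the conservative reading of the protocol.

Folds are additionally stratified: groups are shuffled, blocked by their
majority label, and dealt to folds in one global cycle. This spreads each
class across folds as far as atomicity permits, avoids empty-class folds for
rare classes, and reduces exactly to leave-one-out when every group is a
singleton and k equals the group count. A fold whose training complement
lacks a class aborts with a diagnostic rather than silently fitting a
two-class model.

`run_cv()` reports both the pooled out-of-fold confusion matrix (N = dataset
size) and per-fold means of the one-vs-rest counts, the latter matching the
convention of published cross-validation tables in this area (fractional
mean counts). Per-fold normalized counts are only computed for folds
containing every class.

# Evaluation

With classes this imbalanced, raw accuracy rewards majority guessing. The
package's normalization multiplies every cell of true-class row i by
w_i = x_ref / x_i, rescaling all true classes to the size of a reference
class (default `no_effect`). This scheme is the unique per-row reweighting
consistent with published raw/normalized report pairs in this problem family
(e.g. a raw increasing-class TP of 14 printing as 38.1 = 14 × 237/87, with
the no-effect row unchanged). Consequences worth knowing, all asserted in
the tests:

* ratio measures computed from a normalized matrix do not depend on the
  choice of reference class (changing reference rescales all weights by a
  common factor);
* sensitivity is unchanged by normalization (a within-row ratio), while
  PPV, NPV and specificity shift, because they pool differently-weighted
  rows — published tables show exactly this pattern;
* the normalized correct prediction ratio of *any* fixed classifier on
  label-independent data is 1/3 for three classes, which makes it the right
  chance baseline under imbalance.

Per-class measures are one-vs-rest: PPV = TP/(TP+FP), NPV = TN/(TN+FN),
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). A 0/0 ratio is reported
as `NaN`, never as 0 — an undefined PPV (nothing predicted into a class) is
information, not a zero score. Overall measures are CPR = Σ z_ii / N and
GC² = χ²/(N(K−1)) with expected cells e_ij = x_i y_j / N; GC² is undefined
(NaN) when a margin is empty. GC² is checked in the tests against R's
independent chi-square implementation on a thousand random matrices.

`reconstruct_confusion()` inverts the publication convention: given printed
per-class raw TP/FP/FN and normalized FP under known weights, the six
off-diagonal cells of a 3 × 3 matrix solve a 2 × 2 linear system per
predicted-class column. The solution is rounded to integers and verified
against the raw marginals exactly and the normalized ones to one-decimal
printing tolerance (0.06 by default); inconsistent marginals, or equal
weights (which make the system singular), raise errors rather than guesses.

# The synthetic generator, and what passing tests mean

`generate_fixture()` produces random 20-letter sequences, samples sites, and
places up to 4 distinct substitutions per site so grouping is exercised.
Class proportions for the noise component default to 3136 : 2166 : 1026
(decrease : no_effect : increase), the imbalance of the curated corpus this
problem family is trained on. With probability `signal` a variant's label
follows a planted rule expressed entirely through visible features —
gaining a hydrophobic residue ⇒ decrease, losing one ⇒ increase, otherwise
decrease in strongly nonpolar windows (NonPolarAA ≥ 14) and no_effect
elsewhere; with probability 1 − `signal` the label is drawn from the class
proportions.

The generator emulates the *structure* of real data — alphabet, notation,
per-site multiplicity, imbalance — not its biophysics: real solubility
effects are not a deterministic function of four residue groups and a window
count, real sequences are not i.i.d. residues, and real labels carry assay
noise and curation thresholds. Passing the planted-signal tests therefore
demonstrates that the pipeline can learn a learnable rule, that RFE finds
planted informative features, and that the protocol and metrics are wired
correctly — not that the shipped feature sets reach any particular accuracy
on real proteins. Test problem sizes (2000 variants for the
learnability checks, 500 × 51 for the RFE retention study over 20 seeds,
a few hundred elsewhere) were chosen as the smallest sizes at which these
properties are stable across seeds.

# Shipped data and stand-ins

`inst/extdata/aaindex_core.txt` carries 19 AAindex property scales, verbatim
from the public AAindex database (the test suite cross-checks one of them,
the isoelectric-point scale, value-for-value against an independent AAindex
snapshot). Three accessions of the default 34-feature set postdate that
snapshot and are unavailable offline; they ship in
`aaindex_synthetic_standins.txt` as clearly labelled **synthetic stand-in
scales** — real accession names so the default feature sets resolve, but
placeholder values, and descriptions that say so. Any analysis caring about
those three scales should supply a current AAindex1 file via
`read_aaindex()`; everything downstream accepts it unchanged.

The bundled substitution-count table (20 × 20 counts of the curated corpus)
stores cell counts only; row and grand totals are recomputed, and the test
suite checks the published marginals (leucine row 659, total 6328) by
summation.

One documented ambiguity in the source literature: the running text and the
tables of the corpus description disagree on which of the two minority
classes has 237 blind-test cases and which 87 (and correspondingly
1929/939 in training). The printed sensitivities resolve it — 237 no-effect,
87 increasing — and the package follows the tables throughout.

# Known limitations

* Sequence-only: no structural context, no conservation (the stub exists but
  returns missing values), so positions that are equivalent in sequence
  composition but different in structure are indistinguishable.
* The shipped default feature sets name three stand-in scales (above);
  training a real model at full fidelity requires a current AAindex file.
* No trained model ships with the package: predictions require training on a
  labeled corpus first (`fit_two_layer()` or the CLI `train` subcommand).
* The normalization scheme assumes every true class is represented; empty
  classes make normalized reports undefined by design.
* Hyperparameters are deliberately plain defaults; no tuning machinery is
  included, and none was used for the shipped feature sets.
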