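---
title: "QSAR classification and Mondrian conformal prediction: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR classification and Mondrian conformal prediction: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpqsar)
```

## The problem

Public bioactivity databases accumulate heterogeneous potency measurements
(IC50, Ki, EC50, ... expressed on the unified negative-log-molar pChEMBL
scale) for thousands of protein targets.  Per-target binary
active/inactive classifiers built from such tables are routinely used to
prioritise compounds, but a plain QSAR classifier offers no formal
confidence for an individual prediction.  Conformal prediction addresses
this: a calibration set turns any probability model into *prediction
sets* that contain the true class with frequency at least $1-\varepsilon$
under exchangeability.  The Mondrian (class-conditional) variant applies
the machinery separately per class, which protects the minority class on
the imbalanced sets that dominate real panels.

`cpqsar` implements both arms and the shared evaluation framework:
curation of raw activity tables into per-target modelling sets, 2054-bit
featurization, a class-weighted Random-Forest QSAR arm, a from-scratch
Mondrian conformal arm, the both/empty-aware metric family, and temporal
validation across two database releases.  A synthetic-study generator
with known ground truth makes every stage testable offline.

## Curation model

Records pass four filters: the standard relation must be `=` (measured)
or `<` (censored below, used as high-quality inactive evidence) with a
pChEMBL value present; potential-duplicate flags, any data-validity
comment, and "inconclusive"/"undetermined" activity comments drop the
record; the source must be in a configurable allow-list (default
literature and DrugMatrix codes 1 and 15).  When one measurement group
carries several activity types the configurable priority list (IC50
first) selects one before aggregation.

Structures are reduced to canonical nonstereo SMILES, so stereoisomers
collapse onto one compound — 2D descriptors cannot distinguish them
anyway.  Replicates per (target, structure) aggregate to the median of
measured values; a structure seen only through `<` records is carried as
censored-inactive.  When measured and censored records coexist the
measured ones win and the censored rows are discarded rather than pooled:
`=` carries strictly more information, and pooling censored values into a
median would mix two different kinds of quantity.

Labels use the Illuminating-the-Druggable-Genome family thresholds
(kinases 7.5, GPCRs 7, nuclear receptors 7, ion channels 5, all other
families 6.5), with *value ≥ threshold* counted active.  A target is
retained only if (i) it is backed by at least two distinct publications —
applied first, before any counting — and (ii) it has at least 40 actives
and 30 inactives under its family threshold, or, failing that, under the
default threshold 6.5 (the same compound set relabelled; `threshold_used`
records which rule fired).

## Features

Each structure maps to 2048 radius-2 circular-fingerprint bits followed
by six physicochemical descriptors, in a fixed order: MolWt, NumHDonors,
NumHAcceptors, NumRotatableBonds, MolLogP, TPSA.  Chemistry is computed
with Open Babel (via ChemmineOB): the ECFP4 fingerprint (4096 bits,
OR-folded to 2048) and Open Babel's property definitions.  Toolkit
conventions differ slightly between implementations — Open Babel counts
amide C–N bonds as rotatable where some toolkits exclude them — which
shifts individual descriptor values but not any protocol-level property.

The six descriptors are min–max scaled.  The scaler is fitted on **each
model's training portion only** and applied to test, calibration and
temporal compounds, which may therefore fall outside $[0,1]$ (no
clipping; a constant column maps to 0).  Fitting per split avoids
information leakage from test compounds into the transform; a
whole-dataset fit would be harmless for these six bounded descriptors
but leakage-free defaults are the safer convention.  The feature backend
is pluggable: a precomputed matrix keyed by structure string serves the
entire modelling stack without any chemistry dependency, which is how
the synthetic studies run.

## Modelling arms and the shared protocol

Both arms use a probability Random Forest (`ranger`): 300 trees, maximum
depth 20, all other parameters at library defaults, recorded in the run
manifest.  "Balanced" class weighting assigns each class the weight
$N/(2\,n_{\text{class}})$.  `ranger`'s `class.weights` argument enters
only the split criterion and leaves terminal-node class frequencies
untouched, so on a ratio-0.15 synthetic target it leaves minority-class
sensitivity at zero; `train_rf` therefore also passes the same weights
as per-observation `case.weights`, which reach the bootstrap draws and
hence the predicted probabilities — the behaviour expected of balanced
weighting in probability forests.

The validation protocol draws, per repeat, a stratified 80/20
train/test split (class proportions preserved within one compound per
class).  The QSAR arm trains on the whole training set.  The conformal
arm further divides the training set 70/30 into a proper training set
and a calibration set; this inner split is stratified — a plain random
split would occasionally produce an empty per-class calibration list on
small imbalanced targets, which is undefined for a Mondrian predictor.
Both arms consume the *same* first-split seeds, so their test sets are
identical repeat by repeat and the comparison is unbiased by set
membership.  The default plan repeats 100 times; per compound, the
median over the repeats in which it fell in the test set is reported
(median $P(\text{active})$ for QSAR, median $p$-value pair for the
conformal arm).  A compound is never predicted by a model it helped
train.  The QSAR hard class uses the conventional
$P(\text{active}) \ge 0.5$ rule.

## Conformal machinery

The conformity score of a compound for a class is the model's predicted
probability of that class.  Calibration produces one sorted score list
per true class.  For a new compound, two p-value definitions are
offered:

* **literal** (default): $p = \#\{s : s < P_{\text{new}}\}/n$ — the
  fraction of calibration scores strictly below the new score, ties
  excluded;
* **adjusted**: $p = (\#\{s : s \le P_{\text{new}}\} + 1)/(n + 1)$ —
  the standard finite-sample-corrected definition whose coverage
  guarantee is exact under exchangeability.

The literal rule mirrors the counting description used in the protocol
this package operationalises; its tie handling and missing $+1$
correction make it very slightly anti-conservative, which is invisible
at realistic calibration sizes but matters for property testing — the
validity test suite therefore runs in adjusted mode, and every output
records which mode produced it.

A class joins the prediction set iff its p-value strictly exceeds
$\varepsilon$; sets are one of single-active, single-inactive, `both`,
`empty`, and are nested across $\varepsilon$ by construction.  Sets are
computed from the *median* p-values over repeats (median-then-assign),
not by voting over per-repeat assignments, matching the protocol's
median aggregation.

## Metrics

Sensitivity and specificity are the per-class correct fractions; CCR is
their mean.  For conformal sets, the `_incl` variants count `both` as
correct with the full class as denominator; the `_excl` variants remove
`both` compounds from numerator and denominator.  `empty` predictions
are errors in both variants — the protocol defines special treatment
only for `both`, and an empty set asserts nothing correct.  This choice
shapes the high-confidence `_excl` numbers: at 90% confidence most
uncertainty flows into `both`, so excluding it lowers rates noticeably.
Validity counts a prediction as an error when the true class is outside
the set ( `both` always contains it); a model is valid at $\varepsilon$
when its error rate is at most $\varepsilon$, overall or per class.
Family aggregation is the unweighted mean over a family's targets — the
reported quantity is "mean of the models", not a compound-weighted
pool.  The Tanimoto diagnostic reports the median similarity over **all
cross-set pairs** between two fingerprint sets (e.g. test vs calibration
compounds of one class); per-test-compound maxima would answer a
subtly different question (nearest-neighbour coverage), and the all-pairs
median is the more conservative summary of set overlap.

## Temporal validation

Given two releases, the workflow restricts to targets modelled in the
earlier one, keeps only later-release compounds whose canonical
structure is absent from the earlier release for that target, labels
them with the *model's* stored threshold (never a re-derived one), and
predicts them with both arms: each repeat trains under the internal
protocol's splits and predicts every new compound, with medians over
repeats.  Because realistic release deltas contribute only a handful of
new compounds per target, metrics are pooled globally; per-target rows
are emitted only above a configurable minimum (default 10 new
compounds).

## The synthetic-study generator

The generator emulates the statistical shape of a curated bioactivity
panel, not its chemistry.  Defaults are fixed study conditions: 400
compounds per target (panel median of a few hundred), active fraction
0.45 (active:inactive ratio near the observed median of 0.8),
separability $s = 0.5$, 10% label noise, 64 informative bits in a
2048-bit fingerprint with background on-rate 0.1, three publications per
target, 30% of inactives censored, and pChEMBL values kept at least 0.3
log units away from the class threshold so labelling is unambiguous.

Informative bits are Bernoulli$(0.5 + s/2)$ for actives and
Bernoulli$(0.5 - s/2)$ for inactives; six pseudo-descriptors come from
class-shifted distributions on realistic native scales.  Label noise
flips the reported label of a rounded fraction of compounds away from
their feature-generating class.  The noise level is what makes the
emulation behave like real panels rather than like a toy: it sets an
irreducible error floor (QSAR CCR near $1 - \text{noise}$, in the range
real panels report), populates the calibration tails that produce
`both`/`empty` predictions, and so reproduces the characteristic
confidence-level trend — `both` grows and `empty` shrinks as confidence
rises — that degenerate noise-free generators cannot show.  Decoy rows
(flagged duplicates, inconclusive comments, data-validity comments, `>`
relations) are injected with *wrong-side* potency values, so any filter
failure corrupts labels detectably instead of silently passing.

What the generator does **not** emulate: real chemical-space geometry,
fingerprint bit correlations, activity-value distributions, or scaffold
clustering.  Passing tests therefore demonstrate correctness of the
machinery and of its statistical properties under exchangeability, not
predictive performance on real extractions, whose headline numbers
require the original database releases.

A temporal pair shares release A and adds a configurable fraction of
new compounds per target, drawn either from the same distribution
(exchangeable — pooled temporal CCR should match internal CCR) or at a
lower separability (drifted chemistry — temporal CCR should fall, the
direction seen in real release-to-release validation).

## Numerical and reproducibility choices

All randomness flows from one master seed through labelled streams
(`derive_seeds`): the first-split stream is shared verbatim by the two
arms; calibration splits and forest seeds use independent streams.
Reruns are byte-identical; `ranger` runs single-threaded by default for
bit-reproducibility.  Stratified splits round per class to the nearest
compound, always leaving at least one compound per class on each side;
classes with fewer than two members refuse to split.  Degenerate scaler
columns map to 0; all-zero fingerprint pairs have Tanimoto similarity 0;
an undefined rate (empty denominator) propagates as missing rather than
as an arbitrary number.

The acceptance-level checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run at deliberately reduced problem sizes chosen
as the package's own desk-scale study: 100-tree forests, 200–400
compounds per target, 3–10 split repeats, 5–50 targets per property.
These sizes keep every estimate stable (medians over repeats, means over
targets) while the full 300-tree / 100-repeat configuration remains the
default for real runs.

## Known limitations

* The chemistry backend follows Open Babel's descriptor conventions;
  numbers differ in detail from other toolkits' implementations of the
  same descriptors.
* Salt stripping, charge neutralisation and tautomer standardisation are
  out of scope; structures are canonicalized as given.
* The literal p-value mode is not guaranteed conservative; use adjusted
  mode when the coverage guarantee matters.
* Family-level aggregation assumes the family label is supplied in the
  input table; no ontology lookup is performed.
* Venn–ABERS predictors, cross-conformal variants and regression
  modelling are intentionally not implemented.
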