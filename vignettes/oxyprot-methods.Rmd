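---
title: "Classifying oxygen-binding proteins from sequence: models, encodings, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying oxygen-binding proteins from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyprot)
```

## The problem

Oxygen-binding proteins (oxy-proteins) occur across the whole tree of
life and fall into six structurally and functionally distinct families:
hemoglobin (HEMO), myoglobin (MYO), leghemoglobin (LEG), erythrocruorin
(ERY), hemerythrin (HEME), and hemocyanin (HCY). Given only a primary
amino-acid sequence, `oxyprot` answers two questions:

1. Is the protein an oxygen binder at all (binary OXY vs NONOXY)?
2. If so, which of the six families does it most resemble?

Both questions are answered with support-vector machines over
fixed-length sequence encodings. SVMs are a natural fit here: the
discriminating signal is a smooth shift in residue-usage statistics
rather than a discrete motif, the feature spaces are moderate (20--420
dimensions), and a margin-based decision score supports the
threshold-resolved evaluation this package reports.

## Feature encodings

Four encodings map a length-$L$ sequence to a fixed-length vector:

* **AC** (20-d): amino-acid composition, $\mathrm{AC}_r = n_r / L$, the
  fraction of each residue $r$.
* **DC** (400-d): dipeptide composition over the $L-1$ overlapping
  ordered pairs, $\mathrm{DC}_{ij} = n_{ij} / (L-1)$, indexed row-major
  with the first residue major over the alphabet
  `ACDEFGHIKLMNPQRSTVWY`. The $L-1$ denominator is the standard choice
  for overlapping windows; dividing by $L$ would differ only by a factor
  $(L-1)/L$ and would not sum to one.
* **PSSM** (400-d): an evolutionary-profile encoding. A
  position-specific scoring matrix (an $L \times 20$ table of
  per-position substitution scores, as produced by iterative
  profile searches such as PSI-BLAST) is first min--max normalized over
  the whole matrix,
  $v' = (v - \min)/(\max - \min)$, so the smallest score becomes 0 and
  the largest 1. The variable-length normalized profile is then reduced
  to 400 dimensions by the residue-grouped row sum: entry $(r, c)$ is
  the sum of normalized column-$c$ scores over positions whose sequence
  residue is $r$, divided by $L$. This is the widely used
  "PSSM-400" reduction; a simpler 20-d per-column mean is available via
  `pssm_composition(reduced = TRUE)`.
* **HYBRID** (420-d): the concatenation `[AC | DC]`.

Two normalization choices deserve comment. The min--max scope is
per-matrix (each sequence's profile is self-normalized), because the
classifier scores single query sequences independently and must not
depend on which other sequences happen to be in a batch; a per-column
scope is available (`normalize_pssm(scope = "column")`). A constant
(degenerate) profile has no range to rescale; it maps to all zeros with
a warning rather than an error, so that batch pipelines survive
low-complexity sequences.

The package never runs PSI-BLAST. Real profiles are supplied as NCBI
ASCII PSSM files (one per sequence id); `parse_pssm()` consumes the
first 20-column log-odds block and remaps columns from the file's
header order to the fixed alphabet. When no profiles exist,
`pseudo_pssm()` synthesizes one from BLOSUM62 rows plus seeded Gaussian
noise (default sd 1.0 on the integer score scale) — a deliberately
simple stand-in that carries residue identity plus noise, not a claim
of PSI-BLAST fidelity.

## Models

`train_bundle()` fits seven binary SVMs sharing one feature mode: OXY
vs NONOXY, plus one one-vs-rest model per family. Sub-class negatives
default to the other five families only (`negative_policy =
"oxy_rest"`), since the sub-class models' job is to discriminate
*among* oxygen binders; the non-oxy pool can be added by configuration.

The SVM layer standardizes features (train-time center/scale stored in
the model and reapplied verbatim at prediction, so there is no
train/serve skew), then fits a libsvm RBF machine (linear by option).
The upstream literature that popularized this family of predictors
used SVM-light without publishing kernel or cost settings, so those
are treated as free method parameters here: the defaults are
$C = 10$, $\gamma = 1/d$, and passing vectors for either triggers a
small grid search by stratified 3-fold inner cross-validation
(accuracy at threshold 0; ties prefer smaller $C$, then smaller
$\gamma$). Class imbalance is handled by inverse-size class weights by
default, or by seeded subsampling of the majority class
(`class_balance = "subsample"`), which mirrors the common practice of
drawing a negative set matched in size to the positives.

Decision scores are computed in-package from the extracted support
vectors, dual coefficients and offset (verified against libsvm's own
decision values), which is what makes the plain-text persistence exact:
`save_bundle()` writes every number at full precision and
`load_bundle()` reproduces scores bit-for-bit.

`classify_sequence()` reports the binary score and all six sub-class
scores ranked; the family call is the argmax, with ties broken by the
fixed order ERY < HCY < HEME < HEMO < LEG < MYO, and a flag notes when
no sub-class score reaches its threshold (the binary verdict is still
reported).

## Evaluation protocol

Evaluation follows the standard protocol for this predictor family:

* **Repeated stratified five-fold cross-validation**
  (`make_folds()`, `cross_validate()`): items are split into five
  near-equal folds (within every class, sizes differ by at most one),
  each fold is held out once, and the whole procedure is repeated
  (default 20 times) with independent partitions. Metrics are computed
  on the pooled out-of-fold scores within a repeat, then averaged over
  repeats — pooling is what yields a single headline accuracy per
  model. Stratification is the default; an unstratified mode exists.
* **Threshold-resolved metrics**: with TP/TN/FP/FN counted at a cutoff
  $t$ (predict positive iff score $\ge t$),
  $\mathrm{ACC} = (TP+TN)/N$, $\mathrm{Sen} = TP/(TP+FN)$,
  $\mathrm{Sep} = TN/(TN+FP)$, and
  $\mathrm{MCC} = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$,
  with the standard convention $\mathrm{MCC}=0$ when any denominator
  factor vanishes (the quotient is undefined there).
  `threshold_sweep()` evaluates the grid $-1.5$ to $+1.5$ (step 0.1, 31
  points — the step is not fixed by convention, so it is configurable)
  and reports grid averages of ACC/Sen/Sep.
* **ROC/AUC** (`roc_curve()`): TPR vs FPR at every distinct score, AUC
  by the trapezoidal rule, which with ties equals the Mann--Whitney
  statistic $P(s^+ > s^-) + \tfrac12 P(\text{tie})$.
* **Cross-class confusion** (`cross_class_confusion()`): every
  oxy sequence is checked against all six family models at their
  thresholds. A sequence accepted by several models is counted in each
  accepting column — this deliberately multi-counting layout captures
  both phenomena of interest (sequences recognized by other families'
  models, and sequences recognized by none). The exact accounting
  identity is therefore per row: sequences accepted by at least one
  model plus the `unrecognized` column equal the class size; the
  single-label view (own model wins the argmax) is exposed as the
  `own_argmax` attribute.

## The synthetic benchmark

The curated sequence sets this method family is trained on (UniProt
keyword extractions, redundancy-reduced at 50%/90% identity) and the
PSI-BLAST-vs-nr profiles behind the PSSM encoding are not
reconstructable at package scale, so `oxyprot` ships a generator that
emulates the *statistical* structure the classifier exploits, making
every pipeline stage testable end to end.

`default_profiles()` builds seven residue-composition profiles from
database-average frequencies, enriching two signature residues per
family (e.g. alanine for leghemoglobin, lysine for hemoglobin, valine
for myoglobin — echoing the direction of the composition shifts
reported for real oxy-protein sets). The enrichment per signature
residue defines the separation level: 0.02 (`weak`), 0.05
(`moderate`), 0.12 (`strong`) probability mass. The `strong` value is
calibrated so the per-residue composition shift is about three
standard errors of a composition estimate at the shortest default
sequence length ($L = 80$, $\mathrm{SE} \approx 0.03$): a regime where
the signal clearly dominates sampling noise, which is what "strong
separation" is meant to denote. Sequence lengths are uniform on
80--300, matching the 101--200 band that dominates real oxy-protein
collections. `generate_sequences()` draws residues i.i.d. from the
profile (or from a first-order Markov chain when a dipeptide-coupling
matrix is supplied — i.i.d. draws carry no dipeptide signal beyond
composition, so the coupling option is what makes DC features
non-redundant). `make_benchmark()` assembles six positive classes plus
a matched-size non-oxy background set (multiplier 1.0 by default,
mirroring the matched negative-set sizes used with the real data) and
a pseudo-PSSM per sequence; everything derives from one seed and
regenerates bit-identically.

What passing recovery tests on this benchmark does and does not show:
it shows the encoders, models and evaluation machinery are correct and
that composition signal of a stated strength is recovered at the
stated rates; it does not show real-data accuracy, because real
families carry homology structure, shared folds, length/composition
couplings and annotation noise the generator deliberately omits.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use six classes of 50
sequences with matched negatives (600 sequences), five-fold CV with 1--3
repeats, and 1000-sequence oracle sweeps — sizes chosen so the whole
suite re-runs in a few minutes while keeping the statistical checks
well-powered (binomial SEs of a few percent at $n = 600$). Encoder
correctness is asserted to $10^{-12}$ (pure counting), persistence and
pipeline self-consistency to $10^{-9}$ (full-precision text round
trips are exact in practice), and stochastic checks use fixed seeds
with 3--3.5 SE bands. Degenerate inputs are handled explicitly:
length-1 sequences encode under AC but are an error under DC/HYBRID
(the prediction layer reports such records as unscorable instead of
failing the batch); constant PSSMs normalize to zero with a warning;
classes smaller than the fold count are spread over fewer folds with a
warning.

## Known limitations

* Decision scores are raw SVM margins; no probability calibration is
  provided or implied.
* The pseudo-PSSM generator does not model alignment depth, position
  heterogeneity, or homology — PSSM-mode results on synthetic data
  measure machinery, not profile informativeness.
* The binary and sub-class models share one feature mode per bundle;
  mixed-mode ensembles are out of scope.
* The generator's class sizes default to balanced; real oxy-protein
  collections are strongly imbalanced (hemerythrin and hemoglobin
  dominate; leghemoglobin is rare), and the class-weighting and
  subsampling options exist for exactly that situation.
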