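---
title: "Methods: multi-target virtual screening of a dual-reporter fibrosis assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-target virtual screening of a dual-reporter fibrosis assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phenotypic high-throughput screens of myofibroblast activation read out two
coupled fluorescent reporters in primary fibroblasts: RFP driven by the
alpha-smooth muscle actin (αSMA) promoter and EGFP driven by the collagen
α1(I) promoter. Both are expressed as fold-over-control intensities, so an
untreated well sits at 1.0 and an anti-fibrotic compound pushes both
readouts below 1. A wet screen of a few hundred compounds is far smaller
than the space of purchasable drug-like molecules; `phenoscreen` extends
such a screen *in silico*: it learns a model from the measured
(compound, RFP, EGFP) triples and predicts both intensities for arbitrary
candidate compounds given only their structures, then turns those
predictions into a prioritized, annotated hit list.

## Compound representation

Compounds enter as SMILES strings. The package parses a restricted but
practical dialect (organic-subset atoms, aromatic lowercase forms, branches,
ring-closure digits and `%nn` labels, bracket atoms with explicit hydrogen
counts and charges; stereo descriptors are accepted and ignored because the
descriptor below is achiral). Implicit hydrogens on bare atoms are resolved
by the smallest standard valence accommodating the bond-order sum; aromatic
bonds count 1.5, and aromatic atoms are held at their default valence so
that, for example, a substituted aromatic nitrogen carries no spurious
hydrogen. Ring membership — part of the atom environment below — is
computed from the graph: an atom is ring-flagged when it touches an edge
that is not a bridge (bridge detection is delegated to `igraph`).

The descriptor is a binary extended connectivity fingerprint (ECFP).
Iteration 0 hashes the per-atom tuple (atomic number, heavy-atom degree,
attached hydrogens, formal charge, ring flag); iteration *r* hashes the
atom's previous identifier together with the *sorted* list of (bond order,
neighbour identifier) pairs, which makes the result invariant to atom input
order. Aromatic bonds keep their own order token rather than a Kekulé
alternation, again for relabelling invariance. All identifiers from
iterations 0..radius are folded into `[0, nbits)` by modulo. Defaults are
radius 2 and 2048 bits — the de-facto community defaults (ECFP4 at a common
folded length); both are configurable. Identical environments arising in
one iteration are not deduplicated before folding: a binary vector collapses
them anyway. All hashing is 32-bit FNV-1a over byte-serialized tuples, so
fingerprints are identical across platforms and process runs — a property
the training-compound exclusion step relies on, since it compares compounds
by exact fingerprint keys.

## The model

The learner is a bagging ensemble of multi-target predictive clustering
trees. A tree node splits its records on one fingerprint bit; the split
score is the reduction in

$$V(S) = \frac{\mathrm{Var}_{S}(\mathrm{RFP})}{s_\mathrm{RFP}^2}
       + \frac{\mathrm{Var}_{S}(\mathrm{EGFP})}{s_\mathrm{EGFP}^2},$$

the within-node population variance summed over the two targets, each
normalized by its full-training-set standard deviation so that both
phenotypes contribute comparably regardless of their dynamic ranges. Leaves
predict the per-target mean of their records, so a single tree predicts a
(RFP, EGFP) prototype jointly — the multi-target aspect is what lets one
model exploit the biological coupling of the two reporters.

Numerical choices, all deliberate:

* **Population variance** (divide by *n*) everywhere, so brute-force oracle
  tests can assert exact equality.
* **Ties** on the variance reduction go to the lowest bit index, for
  determinism.
* **Zero-reduction splits are admissible.** A balanced XOR-structured
  target gives exactly zero first-level reduction although depth-2 recovery
  is possible; requiring strictly positive gain would make such nodes
  leaves. Termination is still guaranteed because a split makes its bit
  constant in each branch, so any root-to-leaf path uses distinct bits.
  Only a floating-point-negative best reduction (or no split satisfying
  `min_leaf`) stops growth, besides node purity (normalized variance below
  1e-12) and the optional depth cap.
* **Degenerate targets**: a zero-variance target would make the
  normalization undefined; its scale falls back to 1 with a warning.

Bagging draws `n_trees` bootstrap samples of size *n* with replacement and
grows one tree per sample. Per-tree seeds are drawn up front from the root
seed, so results do not depend on evaluation order and one integer
reproduces the whole ensemble. Defaults are 100 trees, `min_leaf` 5 and
unlimited depth — conventional bagging settings at the n ≈ 640 scale of the
training screens this package targets; the tree count trades compute for
variance of the reliability score, and `min_leaf` 5 keeps leaf prototypes
from chasing single noisy wells.

The ensemble prediction is the per-target mean of the tree predictions, and
the per-target **population standard deviation across trees is the
reliability score**: where trees disagree, the training data under that
region of chemistry is sparse or noisy. The two targets' sds are kept
separate; the screening filter chooses which one to act on.

## Performance estimation

`kfold_mae()` estimates out-of-sample mean absolute error by k-fold
cross-validation (default k = 10): a seeded shuffle, contiguous fold
blocks (remainder spread one record per fold from the first), one ensemble
per fold. The aggregate MAE pools absolute errors over all held-out
predictions rather than averaging fold means — the two coincide for equal
folds, and pooling stays well-defined when folds differ by one record; fold
means are reported alongside. `reliability_error_correlation()` computes
the Spearman correlation between per-prediction tree-sd and absolute error:
the claim it checks is monotone ("less disagreement, less error"), not
linear, hence ranks with mid-rank ties; a constant sd vector is an error,
not a zero.

## Screening, filtering, grouping

`screen_library()` predicts every candidate. `filter_hits()` applies two
filters, keeping all rows with audit flags:

* **Activity**: predicted RFP ≤ (1 − threshold) × control, default
  threshold 0.25 and control 1.0 — i.e. at least a 25% predicted reduction
  of the αSMA reporter, boundary inclusive. The threshold acts on RFP only:
  αSMA is the phenotype being thresholded, EGFP is predicted but not
  gated.
* **Reliability**: the configured target's tree-sd must lie at or below a
  quantile (default 0.5, computed with R's default type-7 rule) of the sd
  distribution over the full prediction set — keep the more-reliable half.
  When all sds are equal the rule degenerates to keeping everything. A
  quantile was chosen over an absolute sd cutoff because it is
  parameter-light and self-calibrating across retrainings.

`remove_training_overlap()` flags any candidate whose fingerprint key
equals a training compound's (the exclusion is structural, not by name) and
drops candidate-internal duplicates, keeping first occurrences.
`group_by_reference()` labels each surviving hit with the reference drug of
maximal Tanimoto similarity when that maximum reaches τ (default 0.4, a
conventional "related series" cutoff for folded ECFPs), else `"other"`;
ties break by panel order. Grouping by nearest reference under Tanimoto
replaces interactive clustering tools used in exploratory work with a
deterministic, parameter-explicit rule. A per-reference `in_training` flag
recovers the "related to a drug the wet screen never saw" category, and an
optional label-based exclusion list (off by default) supports discarding
pharmacologically undesirable classes such as corticosteroids.

Empty-versus-empty Tanimoto is defined as 0 (the common library
convention): a featureless pair carries no evidence of similarity.

## The synthetic screen generator

Because the package must be fully testable without proprietary screen data,
`simulate_scenario()` builds complete studies. Molecules are assembled by
concatenating SMILES fragments from a fixed grammar (rings, heteroaromatics,
short polar and halogenated chains) with short linkers — legal because ring
numbers may be reused once closed. The ground truth acts **directly on
fingerprint bits**: each of *k* causal bits subtracts its effect size from
both targets, with the RFP and EGFP effects sharing a latent draw (plus
small jitter) to mirror the coupled reporters, then Gaussian noise is added
and intensities clip at zero. Acting on bits rather than latent chemistry
is the key design decision: the tree ensemble's hypothesis class can
represent the ground truth exactly, so recovery tests have a sharp target
(noise-free CV MAE near zero) instead of an irreducible approximation gap.

Causal bits are drawn from the bits actually populated at moderate
frequency in the simulated library (5–20% for the standard scenarios),
not uniformly from all 2048 — a uniform draw would almost surely select
bits no molecule carries and produce a signal-free screen; the moderate
window also keeps the background carrier fraction low enough that hit
enrichment is a meaningful quantity. Scenario defaults echo the scale the
pipeline targets: 640 training compounds, effects 0.3–0.6 (single-bit
carriers clear the 25% activity threshold), and noise sd 0.08 per target,
which puts the irreducible MAE floor at $0.08\sqrt{2/\pi} \approx 0.064$ —
the same order as published cross-validated MAEs for screens of this kind.

The `heteroscedastic` scenario ties its two noise strata (sd 0.02 vs 0.20)
to a *structural* feature: the causal bit with carrier frequency nearest
50%. This matters. Tree disagreement at a test compound reflects the
variability of the leaves it lands in; only if leaves are approximately
pure in the noise stratum — which splitting on causal bits guarantees when
the stratum is keyed to one — does the reliability score track a compound's
own noise level, which is what the sd-vs-error correlation diagnostic
measures. Randomly assigned strata would inflate errors without moving the
sd.

What the generator does **not** emulate: realistic medicinal-chemistry
property distributions, activity cliffs, dose–response, cytotoxicity, or
assay plate effects. Passing tests demonstrate that the pipeline recovers
bit-additive structure–activity signal under calibrated noise and that its
filters, exclusions and groupings obey their contracts — not that the model
generalizes across real chemical series.

## Problem sizes and determinism

The test suite and the acceptance script run the study conditions at their
native scale — 640 training compounds, 2048-bit fingerprints, 100 trees,
10-fold CV, candidate libraries of 1,000–5,000 and a 10,000-compound
noise-calibration sample — with smaller sizes (60–300 compounds, 128–1024
bits, 10–50 trees) for unit-level properties where scale adds nothing.
Every random draw flows from explicit integer seeds; pipelines rerun under
the same configuration and seed regenerate reports, hit lists and CV tables
byte-identically.

## Known limitations

* The SMILES dialect rejects disconnected inputs (salts must be stripped
  upstream) and treats stereochemistry as equivalent; two enantiomers get
  one fingerprint.
* Implicit-hydrogen resolution and the aromatic-valence convention cover
  common pharmaceutical chemistry; exotic valences fall back to zero
  hydrogens rather than erroring.
* Folding to 2048 bits introduces collisions; the training-compound
  exclusion is therefore exact on fingerprints, slightly conservative on
  structures (colliding structures are treated as identical).
* The reliability filter's quantile is relative to the screened library:
  the same compound can pass in one library and fail in another.
* Trees split on single bits; activity depending on strict co-occurrence of
  many rare features is representable but sample-hungry.
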