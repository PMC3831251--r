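---
title: "Predicting antibody class-specific B-cell epitopes from peptide sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibody class-specific B-cell epitopes from peptide sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclass)
```

## The problem

When a B cell recognises a linear epitope — here a peptide of 4 to 50
standard residues — the antibody it ultimately secretes belongs to one of
several heavy-chain classes, and the class determines the effector arm of
the response: IgG drives systemic immunity, IgE allergic inflammation, IgA
mucosal defence. Epitope collections show class-linked sequence signatures
(proline/glutamine enrichment in IgA-inducing epitopes, cysteine/glutamate
in IgE-inducing ones, and class-specific dipeptide preferences), which
suggests the inducing class is partly predictable from primary sequence
alone. `epiclass` implements that prediction pipeline end to end: feature
encoding, one-vs-rest dataset construction, per-class SVM models,
threshold-dependent evaluation, and antigen scanning.

## Model and procedure

### One-vs-rest datasets

For each class the positives are that class's epitopes; the negatives are
the union of the other epitope classes and the non-epitope pool. A peptide
may legitimately carry two class labels; such sequences are kept in every
positive set where they are labeled, purged from negatives, and logged.
Four designs are supported:

* **RealVar** — variable-length peptides, all negatives (realistic class
  imbalance);
* **BalanceVar** — negatives undersampled uniformly without replacement to
  the positive count;
* **RealFix** / **BalanceFix** — the same after normalising every peptide
  to 20 residues and re-deduplicating.

Length normalisation keeps the central 20-residue window of longer
peptides (ties broken toward the N-terminus) and pads shorter ones
symmetrically with `X` (extra pad C-terminal). The pad symbol is inert
everywhere downstream: it contributes to no composition channel, its
windows are excluded from dipeptide counting, it yields all-zero one-hot
blocks, and it is dropped before property-group mapping. Alternatives
(N-terminal anchoring, terminal-residue repetition) exist in the
literature; the central-window rule was chosen because it preserves the
epitope core under both truncation and extension, and it is the only
place the package manufactures non-natural sequence content.
Redundancy removal is exact-string deduplication only — no
similarity-based clustering — so "non-redundant" means "unique".

An independent split holds out a stratified 20% of a dataset for
evaluation after cross-validated training on the remaining 80%.

### Feature encodings

Six encodings map a peptide to a fixed-length vector. Feature order is
frozen (residues `A..Y` alphabetically, dipeptides `AA..YY`
lexicographically) and versioned, so serialized models are portable.

| scheme | dim | definition |
|--------|-----|------------|
| AAC | 20 | percent residue frequencies (sum 100) |
| DPC | 400 | percent ordered-dipeptide frequencies over overlapping windows (sum 100) |
| BIN | 20×20 | position-wise one-hot over a 20-residue window |
| AAP | 400 | DPC weighted elementwise by a fitted dipeptide propensity scale |
| PCP | 10 | per-property means of per-residue physico-chemical values |
| CTD | 7×21 | composition, transition and distribution of 3-group property strings |

The **AAP propensity scale** is `log((f+ + eps)/(f- + eps))` per ordered
dipeptide, where `f±` are dipeptide frequencies pooled over the positive
and negative training peptides and `eps = 1/(window count of the smaller
pool)`, linearly rescaled to `[-1, 1]`. The additive smoothing bounds the
log-ratio and sends dipeptides absent from both pools to exactly zero; the
min–max rescaling makes the feature scale-free. Because the scale is
fitted on data, it is a training-fold artifact: `cross_validate()` refits
it inside every fold, and a trained bundle carries its own copy.

The **PCP table** (version 1, shipped as `inst/extdata/pcp_properties.tsv`)
holds ten per-residue properties: Kyte–Doolittle hydrophobicity,
Hopp–Woods hydrophilicity, Zimmerman bulkiness, hydrogen-bond donor
count, a steric-hindrance parameter, Fauchère amphiphilicity, net charge
at pH 7, isoelectric point, residue volume and Grantham polarity. The
first eight are the conventional choices for epitope work; the last two
(volume, polarity) complete the set of ten with properties that are
standard, mutually non-redundant, and tabulated on all 20 residues. Users
may substitute their own matrix.

The **CTD groups** are the standard seven-property, three-group residue
partition (hydrophobicity, normalized van der Waals volume, polarity,
polarizability, charge, secondary-structure propensity, solvent
accessibility), giving 21 features per property: 3 composition
percentages, 3 transition percentages (unordered adjacent group switches
over the L−1 adjacencies), and per group the sequence positions — as
percent of L — of its 1st, 25%, 50%, 75% and 100% occurrences. The
quantile occurrence index is `ceiling(q × count)` (the common convention;
absent groups report 0), so distribution values are monotone across the
five quantiles.

### Classification

Per class, an SVM (libsvm via `e1071`) is trained on the standardized
encoded matrix; features are centered and scaled with training-fold
statistics because mixed-scale encodings (PCP especially) otherwise
dominate kernel distances. Kernels: linear, polynomial (degree 2–3) and
RBF; the default tuning grid crosses them with `C ∈ {0.01, 0.1, 1, 10,
100}` and `gamma ∈ {0.001, 0.01, 0.1, 1}`, scored by cross-validated
maximum MCC with AUC as tie-break. Decision scores are oriented so higher
means more class-like, and each bundle stores a decision threshold — by
default the score maximizing MCC over internal cross-validated training
scores, so the stored operating point is not optimistically biased by
in-sample scoring. Users can override it: raising the threshold trades
sensitivity for confidence.

Class assignment is deliberately **non-exclusive**: each per-class model
is thresholded independently, a peptide can be called for two classes
(biologically plausible — mixed IgE/IgG responses are documented), and a
peptide below every threshold is called nothing. One-vs-rest is used for
dataset construction only, never to force a single winner at prediction
time.

### Evaluation

Threshold-dependent metrics are sensitivity, specificity, accuracy (as
percentages) and the Matthews correlation coefficient, with `score ≥
threshold` counted positive and the `0/0 → 0` MCC convention for
degenerate tables. The AUC is trapezoidal over all distinct score cuts,
which equals the tie-corrected Mann–Whitney pair-counting statistic; the
test suite asserts that identity to 1e−12 against a brute-force pair
count. Cross-validation (5- and 10-fold, stratified; `folds = n` gives
leave-one-out) scores every peptide exactly once with a model that never
saw it. Reported operating points are **pooled over folds** — one
confusion table from all test-fold scores at a single global threshold —
because that is what a threshold table at a fixed cut measures; per-fold
AUCs are returned alongside for dispersion.

### Antigen scanning

`scan_windows()` slides a fixed window (default 20, the fixed-length
model width) over a protein at a given stride and reports windows
reaching the model threshold; a stride-1 scan of a length-L protein
scores exactly L−w+1 windows, and all coordinates are 1-based inclusive.
Variable-length scanning pools several window lengths (default 8–20).
`map_exact_epitopes()` reports every exact occurrence of every known
epitope, overlaps included. `similarity_search()` ranks known epitopes by
Smith–Waterman local alignment against the antigen under affine gaps
(defaults: match +2, mismatch −1, gap open −10, gap extend −1, i.e. a gap
of length k costs 10 + k); the alignment is delegated to
`Biostrings::pairwiseAlignment()` and the tests verify it against an
independent full dynamic-programming oracle. Substitution matrices beyond
match/mismatch are out of scope (the hook accepts any matrix).

## The synthetic benchmark

No epitope database ships with the package; instead
`generate_benchmark()` builds labeled pools from a seeded generator so
every stage is testable offline. Each class is sampled residue-by-residue
from a tilted first-order Markov chain: the marginal distribution is a
background (uniform by default) reweighted by per-residue
fold-enrichments, and transitions are additionally reweighted by
per-dipeptide fold-enrichments. A first-order tilt is the simplest
mechanism that plants dipeptide signal mechanistically — and the simplest
under which dipeptide composition is strictly more informative than
residue composition, mirroring the observed feature ordering on real
epitopes.

The default `benchmark_spec()` reproduces the real collection shape:
pools of 11981 IgG-like, 2341 IgE-like, 403 IgA-like and 22835 background
peptides (scalable), with the observed signatures planted — Pro/Gln and
ED/FP/PF/PQ/PY/QP in IgA, Cys/Glu and IQ/LA/NA/NE in IgE, AS/GP/WK/YR in
IgG, 3-fold by default — and class-typical length ranges (IgA 4–12, IgE
8–20, IgG and background 4–30). `strong_signal_spec()` is the
closed-loop stress preset: eight dipeptides at 100-fold over lengths
15–35, a near-deterministic dipeptide grammar. The 100-fold strength and
the 15-residue minimum were fixed together once, because the recovery
ceiling of a dipeptide model on this generator is set by short peptides
that contain no enriched anchor residue at all — such peptides are
information-free, and below ~15 residues they cap cross-validated MCC
near 0.9 regardless of model quality.

A strong one-sided tilt necessarily also shifts the chain's stationary
residue distribution, so on `strong_signal_spec()` data the residue
composition encoding inherits much of the planted signal. For comparing
encodings the package therefore provides `matched_marginal_spec()`, where
the two classes tilt the same two transition cycles in opposite
directions: a reversed cycle has the same stationary distribution, so the
marginal residue composition of the two classes is identical by
construction and all class information lives in residue pairing. On that
benchmark residue composition performs at chance (cross-validated MCC
≈ 0.08 at 250 peptides per class) while dipeptide composition reaches
≈ 0.8 — the feature-ordering comparison is run there.

What the generator does **not** emulate: natural residue abundance (a
natural-abundance background can be supplied), positional structure,
length–class confounding beyond the stated ranges, assay noise, homology
between peptides, or any 3D/conformational property. Passing the
closed-loop tests therefore demonstrates that the pipeline recovers
planted compositional signal without leakage — not that real epitopes are
predictable at any particular accuracy. Published accuracies on curated
epitope collections (MCC ≈ 0.44/0.70/0.45 for IgG/IgE/IgA with dipeptide
features) require those collections and their tuned models, which are
deliberately not bundled.

## Numerical choices and degenerate inputs

* Percentages are reported on the 0–100 scale everywhere.
* MCC uses double precision throughout; the denominator is computed as a
  product of square roots in the tests' oracle and as `sqrt` of the
  product in the implementation, and both agree on integer-valued tables.
* Score ties: the ROC walks distinct score cuts only, so tied scores
  enter as a diagonal segment (the pair-counting half-tie correction).
* `balance()` with a negative pool smaller than the positive set
  subsamples positives to the pool and flags the result
  (`attr(ds, "pool_limited")`) instead of failing.
* Zero-variance features are left unscaled (divisor 1) rather than
  producing NaNs; dipeptides absent from both comparison sets get
  `p = 1` with a `degenerate` flag rather than being dropped.
* All sampling (generation, balancing, splitting, fold assignment) is a
  pure function of (input, seed); RNG state is restored after every
  seeded step, so library calls never perturb a user's stream.

## Problem sizes used by the checks

The packaged checks run the full pipeline at sizes chosen to exercise the
documented study shape while staying desk-sized: the pool-arithmetic
checks generate the four pools at full scale (38 k peptides); the
closed-loop recovery check trains 5-fold DPC models at 2000 peptides per
class; the feature-ordering comparison runs 20 seeded replicates at 250
per class; antigen-scan recovery uses 100 simulated 150-residue antigens.

## Known limitations

* Exact-string deduplication does not remove homologous near-duplicates,
  so cross-validation on real collections can be optimistic; a clustering
  step would have to be applied upstream.
* The variable-length server-style protein scan is realized as pooled
  multi-window scanning; scores from different window lengths are pooled
  without length calibration.
* Only the 20 standard residues are supported; peptides with
  non-standard letters are rejected (or dropped under `lenient = TRUE`),
  never translated.
* Motif discovery (MEME/MAST-style) and logo rendering are out of scope;
  `position_preference()` produces the numeric substrate of a two-sample
  logo only.
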