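---
title: "sh2pep: models, rebalancing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sh2pep: models, rebalancing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

SH2 domains recognize short linear peptides containing a phosphorylated
tyrosine. Residues close to the phosphotyrosine (pTyr) carry most of the
binding specificity, and their effects are not always additive: a residue
that is tolerated on its own can become required, or inhibitory, depending on
what occupies a neighbouring position. `sh2pep` builds one classifier per SH2
domain that maps a peptide window to a binding call, using three ingredients:

1. a **non-linear decision function** (polynomial-kernel SVM) able to express
   joint requirements and mutual exclusions between positions;
2. **regularization** (the soft-margin cost `C` and the kernel degree `d`,
   both chosen by nested cross-validation) to keep the added flexibility from
   overfitting;
3. a **semi-supervised rebalancing** step that compensates the scarcity of
   verified non-binding measurements by mining confident non-binders from a
   large pool of unlabeled peptides.

## Peptide windows and encoding

A peptide is reduced to the 7-residue window covering offsets −2..+4 around
the pTyr (offset 0). Windows truncated by a protein terminus are padded with
`-`; padded positions encode as all-zero blocks. The central Tyr is constant
and never encoded. Each of the 6 flanking positions receives a block of 20
indicator dimensions (one per amino acid, fixed alphabetical one-letter
order), giving a 120-dimensional binary vector; the PSSM baseline uses the
same layout without Cys (19 × 6 = 114). Ambiguity codes (`B`, `J`, `O`, `U`,
`X`, `Z`) are accepted but encode as zero blocks with a warning rather than
an error, so that proteome scans survive occasional non-standard residues.
The alphabet ordering and the terminus padding are package conventions — they
are serialized with every model so encodings remain reproducible.

With the inhomogeneous polynomial kernel `K(x, z) = (x·z + c0)^d` the
implicit feature space spans all monomials of the inputs up to degree `d`;
for the 120-dimensional encoding and `d = 3` there are
`monomial_count(120, 3)` = 295240 degree-3 monomials, a ~3·10^5-dimensional
space that is never materialized. `c0 = 1` is the default (it includes all
lower-degree terms, so a degree-2 model can still use purely additive
evidence); `c0` is configurable, and `c0 = 0` gives the homogeneous kernel.

## Dataset compilation

Interaction evidence arrives as per-record measurements: an apparent
dissociation constant (K_d, nM) from affinity microarrays, or an explicit
±1 label from peptide-array surveys. The compilation rules are:

* K_d < 2000 nM defines binding; the boundary is strict (2000 nM is
  non-binding). When a record carries both a K_d and an explicit label that
  disagree, the explicit label wins with a warning.
* A (domain, peptide) pair labeled positive by one source and negative by
  another is discarded entirely from both sides; exact duplicates collapse.
* Positives already present in the primary (peptide-array) source are
  removed from the microarray sources, and per-source unique counts reported.
* Domains with fewer than 40 positives are dropped (`min_positives`,
  configurable): too few instances to support model selection over a
  non-linear hypothesis space. A domain with exactly 40 is kept.

Peptide identity for conflict/duplicate keys is the exact upper-cased 7-mer
window. `simulate_survey_tables()` generates a three-table survey whose
marginal counts reproduce the published compilation this pipeline was
designed around (474 microarray positives of which 227 are unique, 149
cross-source conflicts, 61 array domains of which 10 fall below the
retention threshold), which lets the whole arithmetic be replayed and
asserted in tests without any download.

## Rebalancing by iterative self-training

For some domains confirmed interactions outnumber verified non-interactions
by up to 15:1. `rebalance()` implements the two-branch treatment:

* **Negatives in excess** — positives are duplicated (seeded, with
  replacement) to parity. Plain copying is used rather than synthetic
  interpolation: a large pool of real candidate peptides exists, so there is
  no need to invent plausible sequences.
* **Positives in excess** — negatives are first duplicated to parity and a
  model is trained; all unlabeled pool peptides are scored, and those most
  confidently predicted non-binding (smallest signed decision value, ties
  broken by pool order) are moved into the negative set. The model is refit
  after every batch (self-training convention) and the loop runs until
  parity, a `max_iterations` cap (default 20), or pool exhaustion, in which
  case the remainder is covered by duplication and the result flagged.

The per-iteration batch is `batch_fraction` (default 0.25) of the remaining
deficit, at least one instance. Batch size, refit schedule and confidence
rule are loop-control choices the underlying idea leaves open; they are
configurable and logged in the returned trace. Confidence is the raw signed
decision value — the distance from the separating hyperplane — not a
calibrated probability.

The test suite checks the treatment comparison this procedure is meant to
win: over 20 seeded 15:1 problems, the self-trained model must beat the
untreated model's specificity while losing less sensitivity than a model
given the same number of *randomly* drawn pool peptides as negatives, in at
least 80% of seeds, and ≥90% of mined peptides must be true non-binders
under the generating rule at zero label noise.

## Model selection protocol

Hyper-parameters are the kernel degree `d ∈ {1, 2, 3}` and cost
`C ∈ {0.01, 0.1, 1, 10, 100}` (defaults; both configurable). The outer loop
is a stratified 5-fold cross-validation repeated 5 times, or repeated 75/25
random splits; the inner loop is a 10-fold cross-validation on each outer
training set, scored by AUC ROC. The most frequent inner winner across outer
training sets becomes the selected configuration, with ties broken toward
smaller degree and then smaller cost (Occam preference; the protocol itself
does not dictate a tie rule). The outer folds are then evaluated with the
modal configuration and reported as mean ± sd of sensitivity, specificity,
precision, AUC ROC and AUC PR. Degenerate fold requests (fewer instances
than folds) reduce the fold count with a warning.

AUC ROC is computed as the normalized Mann–Whitney statistic (ties counted
half), which is exactly the concordant-pair probability; AUC PR is average
precision with step-wise interpolation, which is unbiased under tied scores.
Undefined ratios (empty denominators) are reported as `NA`, never as 0.
`threshold_at_specificity()` implements matched-specificity comparison: the
smallest threshold whose specificity reaches a comparator's, with the
sensitivity at that threshold.

## The PSSM baseline

The comparison baseline scores a peptide by `vec(W)·x` where `W` is a 19 × 6
matrix (Cys excluded) of position-specific frequency differences between the
positive set and a background set, and `x` is the 114-dimensional encoding.
The raw score is divided by a reference score — the raw score at the top
`percentile` of a large tyrosine-window population — so that a relative
score ≥ 1 (boundary inclusive) predicts binding. The default percentile 4.5
is the mean of the two values (3.5, 5.5) that F-measure optimization
produced on two representative domains in the original baseline's
calibration; the exact weight transform of that tool is not recoverable, so
the package implements the plain frequency-difference matrix with an
optional log-odds transform (pseudocount 1) behind a flag, both documented
as interpretations. This scorer is strictly linear in the encoding, which is
the mechanism probed by the mutual-exclusion tests: on balanced XOR rules it
performs at chance while a degree-2 SVM exceeds 0.9 AUC.

## Proteome scanning

`scan_proteome()` applies trained models proteome-wide under three
eligibility filters: the site must be a tyrosine, it must be an
experimentally verified phosphosite, and the peptide's protein must share at
least one subcellular-localization term with the domain-bearing protein.
Proteins without any localization annotation are skipped entirely, as are
unknown protein identifiers (with a warning, never silently). The filters
commute; every emitted prediction satisfies all three, which the tests
re-check post hoc. Within a domain, predictions are ranked by non-increasing
decision value with ties broken by (protein, site) for determinism; the top
`k` (default 50) are reported per domain. Peptides predicted positive by
more than `promiscuity_threshold` (default 40) distinct domains are listed
separately as promiscuous. Localization matching is exact term equality —
ontology-ancestor expansion, if wanted, is a pre-processing step. Site
coordinates are 1-based on the protein sequence.

## The synthetic-data generator

`make_rule()` and `sample_problem()` generate ground-truth binding problems
with the statistical structure the method assumes:

* **Additive rules** (`n_pairwise = 0`): i.i.d. normal position weights; a
  linear discriminant is Bayes-optimal, so degree-1 models should win model
  selection on them.
* **Joint-requirement rules** (`type = "and"`): additive weights
  (sd 0.5) plus pairwise terms of effect 3 requiring amino acids from two
  6-residue position sets simultaneously — neither set member is sufficient
  alone.
* **Mutual-exclusion rules** (`type = "xor"`): binding iff exactly one of
  two 3-residue position sets is matched. These rules carry a position-biased
  background giving each set probability 0.5 at its position (emulating the
  compositional bias of a motif's key positions), which makes every single
  residue marginally uninformative: linear models and PSSMs are provably at
  chance, while the joint occurrence is learnable by a quadratic kernel at
  the sample sizes used. The set size 3 keeps the number of relevant
  quadratic features small enough that 500 instances per class suffice.

Thresholds of additive/joint rules are calibrated against 20 000 seeded
background windows so the background positive rate matches the requested
prevalence (default 0.25 — a pool in which a quarter of candidate peptides
are true binders, which is what makes randomly drawn pool "negatives"
harmful and confidence-mined ones useful). Labels flip symmetrically with
probability `noise_rate`; requested class counts are exact in the observed
labels via rejection sampling with a budget (default 10^6 draws; exhaustion
is an explicit error). The background is uniform over the 20 amino acids
unless a rule or caller supplies frequencies — no attempt is made to mimic
the residue composition of the real human phosphoproteome, and real
measurement error is not a symmetric flip. Passing tests on these problems
therefore demonstrates the machinery (encoding, kernels, rebalancing,
selection, scanning) under controlled conditions, not performance on real
binding data.

## Problem sizes and numerical choices

The test and acceptance computations use: 500 instances per class for the
single-rule XOR separation, 51 simulated domains at 200 training and 150
test instances per class for the linear-vs-polynomial comparison, 20 seeds
of 150 positives / 10 negatives / 1000-peptide pools for the rebalancing
comparison, and reduced selection protocols (grids {1,2} × {1}, 3 outer and
4 inner folds) where full nested selection would be disproportionate. These
sizes were chosen to give stable estimates of each qualitative property at
desk scale.

Other numerical conventions: libsvm optimization tolerance 1e-3 (recorded in
the serialized model); decision values are always recomputed from the stored
support-vector expansion so serialized models are bit-reproducible
(round-trip agreement < 1e-12 is asserted); predictions use `score ≥
threshold`; all fold assignments, duplications and samplings are driven by
explicit seeds, and the pipeline derives per-domain seeds from one global
seed.

## Limitations

* Models are per-domain; there is no cross-domain transfer, and domains
  dropped by the 40-positive filter get no model.
* The PSSM baseline is a reimplementation from the published description,
  not the original tool's trained matrices.
* The scan's localization filter uses flat term equality, not the ontology
  hierarchy.
* Reported performance on synthetic rules does not translate into expected
  accuracy on experimental binding data; the package's claims about real
  data are limited to faithfully implementing the compilation arithmetic and
  the training protocol.
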