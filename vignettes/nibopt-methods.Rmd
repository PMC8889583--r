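---
title: "Methods: negative-image rescoring and greedy cavity-model optimization"
author: "nibopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative-image rescoring and greedy cavity-model optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nibopt)
```

## Overview

`nibopt` scores rigid docking poses against a cavity negative-image (NIB)
model — a set of pseudo-atoms filling the binding pocket — and prunes that
model, one atom per generation, to maximize a virtual-screening enrichment
metric on a labelled training set. This vignette documents the model, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic benchmark does and does not establish.

## Rigid similarity scoring

### Shape

Each atom (pseudo-atom or ligand atom, hydrogens included) is a spherical
Gaussian $\rho_i(r) = p\,e^{-\alpha_i |r - r_i|^2}$ with fixed amplitude
$p = 2.7$ and width chosen so the Gaussian integrates to the atom's
hard-sphere volume $\tfrac{4}{3}\pi R_i^3$:

$$\alpha_i = \pi \left( \frac{3p}{4 \pi R_i^3} \right)^{2/3}.$$

Radii are Bondi values (C 1.70, N 1.55, O 1.52, H 1.20, S/P 1.80, halogens
per Bondi; unknown elements default to 1.70 Å). The overlap of two
structures is the first-order sum of pairwise Gaussian product integrals —
no inclusion–exclusion corrections — and shape similarity is the Hodgkin
index $2\,O_{AB}/(O_{AA} + O_{BB}) \in (0, 1]$. The index is symmetric,
exactly 1 for identical atom sets, invariant under common rigid motions,
and needs only a consistent *ranking* signal, which is why the fast
first-order form suffices. Tests verify it against brute-force grid
integration (0.05 Å spacing, 8 Å box) to 1e-3 on random small structures.

Poses are never translated, rotated, or conformationally adjusted: the
docking engine's placement is what gets scored.

### Electrostatics

Both structures' Coulomb potentials,
$V(x) = \sum_k q_k / \max(|x - r_k|, \varepsilon)$ with softening
$\varepsilon = 0.5$ Å, are sampled at the union of the two structures' atom
centres and compared with the Hodgkin index $h \in [-1, 1]$, reported as
$(1 + h)/2$ so shape and ESP share one scale and a 50/50 blend is
meaningful. If either charge set is identically zero the neutral value 0.5
is returned. Charges are read verbatim from the MOL2 charge column — the
package never derives them.

Two numerical decisions deserve note:

* **Observer points are atom centres**, not a molecular-surface mesh. At
  pseudo-atom resolution a mesh adds cost and a meshing tie-break without
  changing rankings; centres keep the sampling deterministic and mesh-free.
* **Softened self-terms are kept.** Excluding a structure's own
  contribution at a coincident observer point looks harmless but is not:
  for a pose lying within the softening radius of the model (the typical
  near-match), the structure's own charge would be excluded at its centre
  while the partner's near-coincident charge still contributes, which
  *inverts the sign* of the comparison — a correctly docked, correctly
  charged ligand would score as anti-correlated. With the softened
  denominator every self-term is the finite $q/\varepsilon$, identical
  structures score exactly 1, charge-negated copies exactly 0, and
  similarity decays monotonically with jitter.

### Combination and aggregation

The combined score is $w\,S_{shape} + (1 - w)\,S_{esp}$ with
$w \in [0, 1]$; $w = 0.5$ is the default 50/50 weighting and $w = 1$ is
shape-only mode (in which the ESP term is not evaluated). Each compound is
represented by its best-scoring pose — an argmax, so uniform rescaling of
scores changes nothing. Scoring is embarrassingly parallel over compounds
and contractually identical for any worker count.

## Enrichment metrics

* **Ranking.** Scored compounds sort by descending best score, ties keeping
  input order (stable). Compounds skipped by docking are appended at the
  bottom in a uniform random permutation drawn from a recorded seed — the
  order corresponding to random picking — so models remain comparable when
  docking fails for some compounds. An expected-value (analytic) treatment
  of the skipped block was considered and rejected in favour of the
  explicit seeded shuffle, which reproduces an actual screening deck order.
* **AUC** is the Wilcoxon–Mann–Whitney pair statistic (ties count 1/2) with
  the Hanley–McNeil standard error, $Q_1 = A/(2-A)$,
  $Q_2 = 2A^2/(1+A)$.
* **EFd x%** walks the ranking until $\lceil x\% \cdot n_{decoys} \rceil$
  decoys have been seen and reports the percentage of actives found
  strictly before that decoy. Ceiling plus strict counting is the
  conservative deterministic reading of "x% of decoys discovered"; no
  interpolation between integer decoy counts is attempted.
* **BEDROC(α)** follows the Truchon–Bailey closed form; α = 20 weights
  roughly the top 8% of the ranking. Tests cross-check it by an independent
  route (min–max rescaling of the observed RIE against explicitly
  constructed best/worst rankings) and against its small-α limit, the AUC.
* **ROC curves** emit one point per distinct score level, so tied scores
  become diagonal segments and the trapezoid area equals the tie-aware AUC
  exactly (asserted to 1e-12).

## The greedy search

Per generation, all single-atom-removal variants of the current model are
scored and measured with the target metric (default BEDROC(20); AUC and
EFd are available — EFd makes a brittle objective because it reacts only to
changes at one point of the ranking). The best variant is accepted iff its
metric **strictly** exceeds the parent's, compared at full floating-point
precision with no tolerance; among tied best variants the lowest removed
atom index wins. Strictness plus the index tie-break makes the search
deterministic: identical inputs, configuration and seed give identical
results regardless of worker count, which the test suite asserts by
comparing entire result objects.

The search stops when no removal improves the metric, when a generation cap
is hit, or at the `minModelSize` floor (default 3 atoms — one- and two-atom
models make shape similarity meaningless). A run pruning $n$ atoms down to
$a_1$ by single steps costs exactly $\sum_{k=a_1}^{n} k$ variant
evaluations — each accepted generation at size $m$ tests $m$ variants, and
the terminating generation tests $a_1$ — against
$\sum_{k=a_1}^{n} \binom{n}{k}$ for exhaustive subset search. We read the
greedy count as *including* the terminating generation; that reading
reproduces the canonical 495 for a 50-atom model optimal at 40. Being
greedy, the search can stop in a local optimum; it trades the guarantee of
a global one for a tractable evaluation count.

**Cut-and-go** screens every single deletion of the input once, removes all
individually-improving atoms simultaneously (if that would undershoot the
size floor, the weakest improvers are kept), then resumes the standard
loop. It returns the same result object as the standard search — including
the one-pass record as generation 0 — because its evaluation count and
trajectory are part of its contract. Simultaneous removals can interact, so
its final metric may trail the standard search's; on the planted benchmark
it reaches its endpoint in a fraction of the evaluations.

**Merging** concatenates models sharing a coordinate frame (e.g. adjacent
subpockets), optionally collapsing same-element atoms within 0.25 Å of an
earlier atom. The merged model is ordinary input for the optimizer.

Training metrics are always computed on the training compounds only;
held-out evaluation is a separate, explicit call — the package never peeks
at the test set during optimization.

## Training/test splits

`randomSplit()` shuffles each class independently with a seeded
Mersenne-Twister generator and sends the first
$\mathrm{round}(n_{class} \cdot f)$ compounds (at least one per non-empty
class) to training. Stratification is the default so both sides keep the
active:decoy ratio; nearest-integer rounding is used (a 10% draw from 90
actives yields 9). Seeds are recorded in the split manifest; different
well-specified PRNGs would give different but equally valid splits, so no
bit-level split is treated as canonical.

## The synthetic benchmark

`fixtureSpec()` defaults define the standard desk-scale scenario: a 16-atom
cavity model (8 signal + 8 noise), 30 actives, 300 decoys, 3 rigid poses
per compound, 0.3 Å per-coordinate pose jitter, and a decoy subpocket 6 Å
from the signal centre.

* The **signal cluster** is a compact lattice at the origin; the **noise
  cluster** is the same lattice displaced 6 Å — more than 2 Å outside the
  active-pose envelope, so noise atoms never reward actives and their
  removal genuinely helps.
* The lattice spacing is 2.2 Å, chosen so neighbouring Gaussians'
  cross-overlap stays small against their self-overlap. Consequence: a
  pose's self-volume is nearly proportional to its atom count whatever its
  geometry, and removing one cavity atom reorders only the compounds that
  actually use it. At denser spacings the Hodgkin denominator couples every
  compound to the model size and single removals can *demote* actives —
  a real effect, but one that makes a planted-recovery benchmark
  ill-conditioned.
* **Actives** are random ~75% subsets of the signal cluster, jittered per
  pose, with matching charges.
* **Shape-mismatched decoys** straddle the clusters: a composition cycle
  (weighted toward single-noise-anchor "hard" decoys, anchors walking the
  noise cluster round-robin) guarantees that every noise atom supports
  decoys that rank among the actives until that atom is pruned.
  **Charge-mismatched decoys** sit on the signal with negated charges and
  exercise the ESP channel; under shape-only scoring they are
  indistinguishable from actives by construction.
* `skipFraction` marks compounds as skipped by docking (no poses emitted);
  the default is 0 and tests set it explicitly where the skipped-compound
  policy is under test.

All randomness derives from the spec's seed; identical spec and seed give
byte-identical files. The ground truth (signal vs noise atom indices) is
recorded so recovery is measurable.

What passing the planted-recovery test shows: the scoring, ranking, metric
and search layers compose correctly, and the optimizer finds structure that
is genuinely there. What it does not show: performance on real chemistry.
Real ligands have bonded topology, conformational strain, property-matched
decoys and charge models far richer than two-cluster Gaussians; no synthetic
result here predicts enrichment on a real target.

## Problem sizes and determinism in the test suite

Unit and property tests run on a reduced benchmark (6 + 4 cavity atoms, 10
actives, 40 decoys, 2 poses) so the full greedy loop executes in seconds;
the end-to-end recovery check runs the default 16-atom benchmark with a
70:30 split. Determinism checks compare complete optimization results
across repeated runs and across 1 vs 8 workers. Grid-integration oracles
use 0.05 Å spacing in an 8 Å box, where the separable-Gaussian construction
keeps the oracle itself fast.

## Known limitations

* First-order Gaussian overlaps slightly overestimate volumes of strongly
  overlapping atom sets; fine for ranking, wrong for absolute volumes.
* The ESP sampling at atom centres is coarse for charge distributions whose
  differences live far from any atom.
* Greedy search finds local optima; restarting from a pruned model cannot
  escape them (a restart performs exactly one failed generation).
* The MOL2 reader implements the SYBYL dialect the surrounding tools emit
  (one name line per record, ninth atom column = charge); it is not a
  general MOL2 validator.
* Only deletion is searched — atoms are never added, moved, or recharged.
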