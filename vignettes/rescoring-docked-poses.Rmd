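---
title: "Rescoring docked poses: models, schemes and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring docked poses: models, schemes and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockrescore)
```

## The problem

Docking software produces, for a known binder, a small ensemble of candidate
binding poses (AutoDock Vina returns at most nine) together with an estimated
free energy of binding. In virtual screening the experimentally determined
(crystal) pose is almost never available, so binding affinity must be
predicted from a *docked* pose that carries geometric error relative to the
true bound geometry. `dockrescore` implements the machinery to study and
correct the effect of that error: feature extraction from poses, four scoring
models of increasing flexibility, six rules ("schemes") for choosing which
pose(s) of a ligand supply the features, and the standard evaluation metrics.
A seeded synthetic-complex generator makes the entire pipeline testable
without any external dataset.

## The scoring models

**Model 1 (Vina, fixed weights).** Vina's score for the $k$-th pose is

$$e'_k = \frac{e_{k,\mathrm{inter}} + e_{k,\mathrm{intra}} -
e_{1,\mathrm{intra}}}{1 + w_6 N_\mathrm{rot}}$$

where each energy block is a weighted sum of five pair-interaction terms
(two attractive Gaussians, a steric repulsion, a hydrophobic ramp and a
hydrogen-bond ramp) summed over atom pairs within an 8 Å interatomic cutoff,
inter-molecularly (receptor--ligand) and intra-molecularly (ligand atom pairs
that can move relative to each other). Every pair term is a function of the
*surface distance* $d = r - R_i - R_j$ (interatomic distance minus
van-der-Waals radii). The published weights $w_1 \ldots w_6$ are hard-coded
(`vina_weights()`) and never re-fitted; predictions are reported in pKd units
via the linear conversion $pK_d = -0.73349480509\,e$. When the scored pose is
the best-ranked one the intra blocks cancel exactly, which the tests assert.

The five functional forms and their parameters (Gaussian widths 0.5 and 2 Å,
Gaussian-2 offset 3 Å, hydrophobic ramp on $[0.5, 1.5]$ Å, hydrogen-bond ramp
on $[-0.7, 0]$ Å, cutoff 8 Å, the Vina radius table) are the canonical Vina
ones: the out-of-the-box behaviour of the software is the only self-consistent
reading. Likewise, the conversion factor is applied to the rotor-penalized
score $e'_k$ as reported by the software.

**Model 2 (MLR::Vina).** The 11 unweighted features -- 5 inter terms, 5 intra
terms, $N_\mathrm{rot}$ -- feed an ordinary least squares fit. Because the
rotor penalty makes the score non-additive, $w_6$ is found by grid search:
stage 1 enumerates the 101 values $0.00, 0.01, \ldots, 1.00$; stage 2
enumerates the 31 values $0.000, 0.001, \ldots, 0.030$, the interval where
stage-1 optima are always found. For each candidate, the pose-dependent
features are divided by $1 + w_6 N_\mathrm{rot}$ ($N_\mathrm{rot}$ itself is
pose-invariant and enters untransformed) and OLS fits the rest. The final
$w_6$ is taken from the stage-2 grid (ties resolved toward the smaller
value).

**Models 3 and 4 (RF::Vina, RF::VinaElem).** Random-forest regression on the
11 Vina features, or on the 47-feature union with the 36 elemental contact
counts $x_{ij}$ = number of (ligand element $i$, protein element $j$) pairs
within `d_cutoff` of each other (9 ligand elements C, N, O, F, P, S, Cl, Br,
I × 4 protein elements C, N, O, S). The training protocol is: 500 trees per
forest; for each of 10 random seeds, every `mtry` from 1 to $P$ is tried and
the one with the lowest RMSE on the out-of-bag (OOB) predictions is kept.

**Selection modes.** The original benchmark protocol picked the final $w_6$
and forest seed by lowest RMSE *on the test set*; that is a reporting
convention, not deployable practice. Both are implemented: replication mode
(`selection = "test"`) and deployment mode (the default), which uses 5-fold
cross-validation for the MLR grid and OOB RMSE across forest seeds. The CV
fold assignment is deterministic (cyclic by row order) so fits are
reproducible without hidden RNG state.

No forest package is bundled in the target environment, and the OOB-driven
protocol is central here, so the regression forest (bagged CART trees with
variance-reduction splits, node size 5, per-node feature subsampling) is
implemented in C++ under `src/`. It is seeded by its own Mersenne-Twister
stream, making ensembles bit-reproducible across platforms independent of
R's RNG.

## Pose-selection schemes

| scheme | pose(s) used | features (vina11 / vinaelem47) | use |
|---|---|---|---|
| 1 | crystal pose | 11 / 47 | train + test |
| 2 | best Vina score | 11 / 47 | train + test |
| 3 | lowest RMSD vs crystal | 11 / 47 | train only |
| 4 | score closest to measured affinity | 11 / 47 | train only |
| 5 | all nine docked poses | 91 / 415 | train + test (with itself) |
| 6 | two best-scored poses | 21 / 93 | train + test (with itself) |

The printed feature counts are only arithmetically consistent if
$N_\mathrm{rot}$, the one pose-invariant feature, appears exactly once; the
pose-dependent block is therefore 10 (or 46) values and every vector obeys
$\mathrm{len} = m(B-1)+1$. Ligands with fewer poses than a multi-pose scheme
requires are padded by repeating the best-scored pose's block. Blocks are
ordered by ascending Vina energy (rank order) -- the source protocol does not
state its ordering, so this is the documented package choice, as is breaking
selection ties by lowest rank. Scheme 4 compares the Vina score to the
measured affinity *after* pKd conversion, since comparing kcal/mol to pKd
directly would mix units.

## Metrics

RMSE is the plain root mean square prediction error; SD is the residual
standard deviation (with $N-2$ denominator) of the linear regression of
measured on predicted affinity; Rp is the Pearson product-moment correlation
and Rs its rank (Spearman) version, with ties given average ranks (midranks;
the source is silent on ties). Pose error is the heavy-atom coordinate RMSD
between docked and crystal poses in the shared receptor frame: **no**
superposition and **no** symmetry correction, matching the atom-indexed
definition. Atom correspondence is by file order, which Vina preserves; for
topologically symmetric ligands this can overstate the error. Redocking
success is RMSD strictly below 2 Å, reported both for the best-scored pose
and for any pose.

## Numerical and boundary conventions

* Contact counting uses $H(0)=1$: a pair at exactly `d_cutoff` counts as
  inside. The Heaviside convention at zero is ambiguous in the defining
  formula, so the inclusive choice is fixed and tested.
* `d_cutoff` defaults to 12 Å, the original elemental-contact convention;
  the source protocol never states its value, so it is exposed as an
  argument everywhere.
* The pair-term cutoff is 8 Å on the *interatomic* distance (Vina's
  convention), not on the surface distance.
* Intra-molecular pair eligibility: heavy-atom pairs in different rigid
  bodies of the rotatable-bond tree and more than three consecutive covalent
  bonds apart. Bonds are inferred from distances (1.15 × summed covalent
  radii); rigid bodies come from the `ROOT`/`BRANCH` records, so a ligand
  without branch records is rigid and has zero intra terms.
* `TORSDOF` takes precedence for $N_\mathrm{rot}$; absent that, the number
  of `BRANCH` records is used.
* Rank-deficient OLS designs (e.g. scheme 5's 91 features on a small
  training set) are fit by pivoted QR with aliased coefficients set to zero,
  with a warning -- predictions remain well defined.
* The OLS intercept is included by default (the source is silent);
  `intercept = FALSE` reproduces a strictly additive Vina-form model.

## The synthetic generator: what it does and does not establish

`make_complex()` builds a ligand as a self-avoiding heavy-atom chain (bond
length 1.5 Å, 12--24 heavy atoms, element frequencies typical of drug-like
molecules, 0--4 rotatable bonds, polar hydrogens on some N/O) centred in a
pocket of 60--110 receptor atoms placed 2.9--7.2 Å from ligand atoms, close
enough that every term class (including repulsion and hydrogen bonding) is
exercised. Docked poses are rigid rotations (up to 40°) plus a translation of
exactly the configured magnitude (default 1.5 Å) plus per-atom jitter
(SD 0.3 Å), then scored and ranked with the Vina function. Pure translation
with zero rotation/jitter gives poses of exactly known RMSD, which anchors
the RMSD tests.

Affinities are drawn as $y = f(\text{features of a designated pose}) +
\mathcal{N}(0, \sigma)$ with $f$ returned for recovery tests: linear in the
rotor-transformed Vina terms (true $w_6 = 0.02$), exactly the fixed Vina
prediction, linear in a few contact counts, or a smooth saturating nonlinear
response that forests can learn but OLS cannot. Default noise is 0.3 pKd and
affinities are rescaled to span 6.5 pKd units, echoing the wide dynamic range
of real affinity benchmarks at reduced width. Tying $y$ to *crystal*-pose
features while models see *docked*-pose features reproduces the
pose-generation-error setting; the tests confirm, over ten replicate worlds,
that forests trained on docked features beat crystal-trained forests when
tested on docked features -- the package's central qualitative claim -- and
that growing the training set does not hurt test RMSE (compared between the
smallest and largest sizes; intermediate sizes fluctuate at desk scale).

These fixtures have no physical realism: no sterically sensible chemistry, no
protonation states, no correlation structure between pocket composition and
affinity beyond what $f$ injects. A green test therefore establishes that the
algorithms are implemented correctly and that the error-correcting training
strategy works *when the generating process matches the stated world* -- it
does not reproduce any published benchmark number, which would require the
curated experimental datasets and the authors' docking runs.

## Scaling of the test suite

Test forests use tens of trees, two to three seeds and reduced mtry grids;
the protocol code path is identical to the 500-tree/10-seed defaults, only
the constants differ. This keeps the full suite within minutes on one CPU.

## Known limitations

* PDB receptors (without AutoDock types) get synthesised types; O/S default
  to their acceptor forms and donor hydrogens are only recognised via
  explicit `HD` atoms, so hydrogen-bond terms on bare PDB input are
  approximate.
* The exact van-der-Waals radius table of other Vina builds may differ in
  late decimal places; radii are exposed in one internal table.
* Symmetry-equivalent atom relabeling is not applied in RMSD; symmetric
  ligands can report inflated pose error.
* Conformational search / pose generation is out of scope: poses are inputs.
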