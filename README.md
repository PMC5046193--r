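# dockrescore

Rescoring protein–ligand docking poses with Vina interaction terms,
elemental contact features and random forests.

## What this is for

Docking programs generate candidate binding poses of a small molecule in a
protein pocket and score them with an empirical free-energy function. In
prospective virtual screening the affinity of a compound must be predicted
from a *docked* pose, which deviates geometrically from the (usually
unavailable) crystal pose — the *pose generation error*, quantified as the
heavy-atom RMSD between the two. `dockrescore` is a toolkit for building and
evaluating scoring functions under that error, for computational chemists and
method developers. Its central capability is the error-correcting training
strategy: calibrating a scoring function on re-docked poses, rather than
crystal poses, so the model directly learns the map from docked geometry to
measured affinity.

At its core are:

* **Vina features** — the five pair-interaction sums (Gauss1, Gauss2,
  Repulsion, Hydrophobic, HBonding), each a function of the pair surface
  distance `d = r − R_i − R_j`, computed inter- and intra-molecularly, plus
  the rotatable-bond count `N_rot`. The composite score
  `e'_k = (e_inter + e_intra − e_1,intra) / (1 + w6·N_rot)` with the
  published weights, converted to affinity as `pKd = −0.73349480509·e`.
* **Contact features** — the 36 occurrence counts
  `x_ij = Σ_k Σ_l H(d_cutoff − d_kl)` of ligand-element *i* / protein-element
  *j* atom pairs (9 × 4 elements, default cutoff 12 Å).
* **Four models** — fixed-weight Vina; MLR::Vina (two-stage grid on `w6`,
  101 then 31 candidates, + OLS); RF::Vina and RF::VinaElem (500-tree CART
  forests, mtry selected per seed by out-of-bag RMSE, 10 seeds).
* **Six pose schemes** — crystal / best-scored / lowest-RMSD /
  affinity-closest / all-nine / top-two pose feature assembly, with the
  documented padding rules (feature lengths 11, 47, 91, 415, 21, 93).
* **Metrics** — RMSE, residual SD (N−2), Pearson Rp, Spearman Rs, unaligned
  heavy-atom pose RMSD, redocking success rates at the strict 2 Å threshold,
  and the pose-error vs prediction-error correlation analysis.
* **Synthetic fixtures** — seeded generators of receptors, ligands, pose
  ensembles of controlled RMSD, and affinities with known dependence on the
  features, so everything above is testable offline.

File I/O is PDBQT-native (multi-MODEL ligand files with `REMARK VINA RESULT`
energies, `ROOT`/`BRANCH`/`TORSDOF` records; receptors with waters removed
and metal ions retained); plain PDB is accepted for receptors and crystal
ligands.

## Worked example

Generate a synthetic benchmark, train RF::VinaElem on best-scored docked
poses (scheme 2), and evaluate on held-out complexes:

```r
library(dockrescore)
cfg <- fixture_config(n_complexes = 60, affinity_model = "nonlinear",
                      noise_sd = 0.3, n_poses = 5)
ds    <- make_dataset(cfg, seed = 7)
train <- ds$complexes[1:40]; test <- ds$complexes[41:60]

train_tab <- featurize_complexes(train, scheme_id = 2,
                                 feature_set = "vinaelem47")
test_tab  <- featurize_complexes(test, scheme_id = 2,
                                 feature_set = "vinaelem47")

fm <- feature_matrix(train_tab)
rf <- fit_forest(fm$X, fm$y, n_trees = 100, mtry_grid = c(4, 8, 16),
                 seeds = 1:3)
rf
#> <vina_forest: 100 trees, mtry=16, seed=2, OOB RMSE=1.199, selection=oob>

evaluate_model(rf, test_tab)
#> <eval_report: N=20  RMSE=0.908  SD=0.802  Rp=0.943  Rs=0.887>

sr <- success_rates(lapply(test, `[[`, "poses"))
#> redocking success: best-pose 80%, any-pose 100%
```

The evaluation line reads: on 20 held-out complexes the forest predicts
affinity with a root mean square error of 0.91 pKd units, a residual SD of
0.80 after the measured-on-predicted linear fit, and Pearson/Spearman
correlations of 0.94/0.89 with the measured values. The success rates say
80 % of test ligands have their best-scored docked pose within 2 Å RMSD of
the crystal pose.

The same workflow is scriptable end to end (`simulate`, `featurize`,
`train`, `score`, `evaluate`, `rmsd`, `matrix` subcommands):

```sh
Rscript exec/dockrescore simulate --out data --n 30 --seed 1
Rscript exec/dockrescore featurize --dir data --scheme 2 \
    --features vina11 --out features.csv
Rscript exec/dockrescore train --train features.csv --model rf-vina \
    --out model.rds --n-trees 100 --seeds 3
Rscript exec/dockrescore rmsd --crystal data/<id>/ligand_crystal.pdbqt \
    --docked data/<id>/ligand_docked.pdbqt
```

`run_experiment_matrix()` reproduces the model × training-scheme ×
test-scheme evaluation table layout (fixed Vina rows duplicated across
training schemes; schemes 3/4 rejected at test time; 5/6 paired with
themselves).

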