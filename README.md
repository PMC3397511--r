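# qsar3d

Grid-based 3D-QSAR in R: CoMFA/CoMSIA molecular interaction fields, PLS
regression with leave-one-out component selection, the full external-validation
battery with the five-condition acceptability gate, StDev\*Coeff contour maps
with OpenDX export, and a planted-signal synthetic benchmark.

## Who this is for

Computational and medicinal chemists modelling a congeneric small-molecule
series: activities (pIC50) regressed on probe-atom interaction fields sampled
over a regular lattice around the superposed series, so that the fitted model
can be read back as 3D regions where bulk, charge or hydrogen bonding help or
hurt potency. The packaged worked example is a series of 71 thiourea MK-2
(MAPK-activated protein kinase 2) inhibitors with its published 53/18
train/test split and published model predictions.

## The core statistics

* **Fields.** CoMFA steric (Lennard-Jones 6-12, sp3 C probe, truncated at
  ±30 kcal/mol) and electrostatic (332 q_i q_p / (D(r) r), +1.0 e probe,
  D(r) = r) on a 2.0 Å lattice; CoMSIA Gaussian similarity fields
  A_q = -Σ_i w_probe w_i exp(-α r²), α = 0.3, for steric/electrostatic/
  hydrophobic/donor/acceptor weights.
* **PLS (NIPALS).** q² = 1 - PRESS/Σ(y-ȳ)² by literal leave-one-out refits;
  components chosen by maximal q²; r²_ncv, SEE = sqrt(RSS/(n-PCs-1)), F, and
  per-field relative contributions Σ|b_j|·sd_j.
* **External validation.** r²_pred = 1 - PRESS_test/Σ(y-ȳ_train)²; RMSEP;
  through-origin slope k = Σyŷ/Σŷ² (predicted on X); Roy's
  r²_m = r²_test (1 - sqrt(r²_test - r²_o)); the acceptability gate
  r²_pred > 0.5, r²_test > 0.6, (r²_test - r²_o)/r²_test < 0.1,
  0.85 ≤ k ≤ 1.15, r²_m > 0.5; y-randomization, bootstrap, repeated k-fold.

## Worked example

```r
library(qsar3d)

# published activity table: 71 compounds, printed predictions, printed split
act <- thiourea_activity()
test <- act$set_label == "test"
validate_external(act$pIC50[test], act$pred_comfa[test], act$pIC50[!test])
#> External validation (n_test = 18)
#>   r2_pred 0.810 | r2_test 0.806 | (r2_test-r2_o)/r2_test 0.013 | k 0.993 | r2_m 0.723 | RMSEP 0.342
#>   gate: acceptable
```

Reading: feeding the published CoMFA test-set predictions through the metric
layer reproduces the published external-validation row (r²_pred 0.810,
k 0.993, r²_m 0.723, RMSEP 0.342) and the model passes all five
acceptability conditions.

The full structure-based pipeline (build/align the series, compute fields,
train and validate, export contours):

```r
rep <- run_pipeline(run_config(mode = "full", models = "comfa",
                               outdir = "study_out"))
```

and the synthetic benchmark with planted ground truth:

```r
gen <- generate_set(synthetic_spec(n_compounds = 60, snr = 10, seed = 1))
sel <- select_components(gen$block$X, gen$activity$pIC50, max_comp = 10)
sprintf("%d components, LOO q2 = %.3f (SNR %.1f)", sel$ncomp, sel$q2, snr(gen))
#> [1] "3 components, LOO q2 = 0.783 (SNR 10.0)"
```

A command-line interface mirrors the stages: `exec/qsar3d synth|align|fields|
train|validate|contour|run` (see `exec/qsar3d --help` after install).

## What is deliberately out of scope

Receptor docking, molecular dynamics, Mold² descriptors, docking-derived
alignments, and reproduction of internal training statistics that depend on
the original proprietary structure preparation (SYBYL conformers, Tripos
force field, Gasteiger-Hückel charges) — see the methods vignette
(`vignettes/qsar3d-methods.Rmd`) for the full account, including why the
packaged 3D structures are a documented reconstruction from printed R-group
names.
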