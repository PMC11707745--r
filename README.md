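# bcstools

QSPR modeling and provisional Biopharmaceutics Classification System (BCS)
classification of small molecules, in R.

The BCS sorts oral drugs into four classes by the 2x2 combination of aqueous
solubility and intestinal permeability; the class drives biowaiver decisions
and early formulation strategy. Measuring both attributes is slow, so
`bcstools` implements the *provisional* route for pharmaceutical scientists
and cheminformaticians: curate structure–property tables, train
gradient-boosting regressors for the four BCS-relevant endpoints — log S
(log10 mol/L), log P, log D (pH 7.4) and Caco-2 log P_app (log10 cm/s) — and
convert predictions into a class with explicit decision rules.

At its core are two rules. Solubility uses the dose number

    D0 = M0 / (V0 · Cs),    Cs = 10^logS · MW   [mg/mL, V0 = 250 mL]

with D0 ≤ 1 meaning high solubility (USP fallback without a dose:
Cs ≥ 0.1 mg/mL). Permeability compares the predicted value against
metoprolol-anchored cutoffs (log P ≥ 1.72, log D ≥ −0.1954,
log P_app ≥ −5.097 → high). For ionizable species,
log D = log P − log10(1 + 10^(pH−pKa)) (acids; sign flipped for bases).
(high, high) → class 1, (low, high) → 2, (high, low) → 3, (low, low) → 4.

The pipeline: `clean_dataset()` (canonicalization, duplicate merging,
inorganic and unfeaturizable removal, audited counts) → `compute_ecfp()` /
`compute_descriptors()` / `build_graph()` / `embed_conformer()` →
`stratified_split()` / `train_regressor()` / `tune_hyperparameters()` /
`cross_validate()` → `predict_bcs()`, plus confusion-matrix evaluation
(`binary_confusion()`, `bcs_confusion()`, `evaluate_table9()`) against
bundled external-validation tables and a synthetic-data generator
(`generate_synthetic_dataset()`) so everything runs offline.

Requires the OpenBabel `obabel` binary on the PATH; 3D conformer embedding
additionally uses a Python interpreter with RDKit.

## Worked example

```r
library(bcstools)

# permeability classification on the bundled 43-drug jejunal permeability table
r <- evaluate_table9(basis = "logPapp")
sprintf("%d/%d = %.1f%%", r$n_correct, r$n, 100 * r$accuracy)
#> [1] "32/43 = 74.4%"
# log P basis: 24/43 = 55.8%, log D basis: 25/43 = 58.1%

# end-to-end class prediction with property models (stubs here; any trained
# bundle from train_regressor() plugs in the same way)
models <- list(logS = function(s) -4.398, logPapp = function(s) -4.5)
predict_bcs("CCO", models, dose = dose_context(M0 = 500, MW = 250))
#> BCS prediction for CCO
#>   logS       -4.398
#>   logPapp    -4.500
#>   MW 250.00 g/mol, Cs 0.009999 mg/mL, D0 200
#>   solubility low, permeability high (basis logPapp) -> BCS class 2
```

The drug dissolves far too slowly for its 500 mg dose (D0 = 200 ≫ 1 → low
solubility) but crosses Caco-2 monolayers fast enough
(−4.5 ≥ −5.097 → high permeability): class 2.

Training on your own data:

```r
rec <- read_property_csv("logS.csv")              # smiles, value[, name]
cur <- clean_dataset(rec, endpoint = "logS")      # 4-step curation + report
ds  <- stratified_split(cur$dataset, seed = 42)   # 80/10/10, label-stratified
tu  <- tune_hyperparameters(ds, n_evals = 50, seed = 42)
mod <- train_regressor(ds, hyperparameters = tu$best_params, seed = 42)
mod$metrics$test                                  # R2 / MAE / RMSE
save_model_bundle(mod, "models/logS")
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/bcstools.R predict --smiles "CCO" --dose-mg 500 --mw 46.07
Rscript inst/cli/bcstools.R make-synthetic --n 500 --seed 42 --out synthetic.csv
```

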