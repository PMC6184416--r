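# cceann

Curative care expenditure (CCE) accounting and neural-network sensitivity
analysis for hospital discharge data, aimed at health-economics and public
-health researchers studying what drives hospitalization expenditure — in
particular for genitourinary-system diseases (ICD-10 N00–N99) in patients
aged 65 and over.

## What it does

Health-accounts studies observe billed curative income $a_i$ per sampled
admission and, per institution, yearbook totals: curative income
$ST_{INC}$, basic expenditure allowance $ST_{ALL}$ and its preventive part
$S_{P,ALL}$. The package:

1. **Apportions** the yearbook totals onto admissions (SHA2011 style) via
   the sharing coefficient $c_i = a_i/(a - a_p)$, where $a$ is the
   institution's sampled income and $a_p$ its preventive part, giving each
   admission

   $$CCE_i = ST_{INC}\left(1-\frac{a_p}{a}\right) c_i + (ST_{ALL}-S_{P,ALL})\,c_i ,$$

   with preventive records excluded and unallocatable ledger money reported
   in an explicit bucket.
2. **Reports** expenditure along the standard dimensions — GBD broad cause
   group, ICD-10 chapter, institution type (with outpatient/inpatient
   split), age band (with per-capita figures) — with conservation
   guaranteed: every breakdown sums to the grand total.
3. **Models** per-admission hospitalization expenditure with a
   single-hidden-layer perceptron (5 tanh nodes, L2-penalized squared
   loss, L-BFGS, ≤1500 iterations) on eight factors: length of stay,
   institution type, insurance type, surgery, gender, institution level,
   age, admission season.
4. **Ranks** the factors with Garson connection-weight sensitivity
   analysis,

   $$Q_i = \frac{\sum_h (|W_{ih}|/\sum_k|W_{kh}|)\,|v_h|}{\sum_j\sum_h (|W_{jh}|/\sum_k|W_{kh}|)\,|v_h|},$$

   averaged over many random-restart fits, with a convergence report on
   the restart checkpoints.
5. **Simulates** province-scale discharge records, institution ledgers and
   population tables with known ground truth, so the whole pipeline is
   testable by parameter recovery.

See `vignettes/cce-methods.Rmd` for the model details and design
decisions.

## Worked example

```r
library(cceann)

cfg   <- sim_config(n_records = 400000, n_institutions = 150, seed = 2024)
sim   <- simulate_dataset(cfg)
alloc <- allocate_cce(sim$records, sim$ledgers)
tabs  <- render_tables(alloc, sim$records, sim$population)
dplyr::mutate(tabs$age_group, expenditure = expenditure / 1e6)
#> # A tibble: 3 × 5
#>   age_group expenditure proportion population per_capita
#>   <chr>           <dbl>      <dbl>      <dbl>      <dbl>
#> 1 0-14             283.       9.68      4469.       63.3
#> 2 15-64           1876.      64.1      32837.       57.1
#> 3 65+              765.      26.2       5136.      149.
```

Expenditure is in million RMB; the 65+ band spends ~2.5× the per-capita
amount of the younger bands, and proportions sum to 100 by construction.
Fitting the expenditure model on the elderly genitourinary inpatient
cohort and ranking the factors:

```r
cohort <- model_cohort(exclude_invalid(sim$records)$records)
split  <- make_splits(nrow(cohort), seed = 2024)
mm     <- encode_factors(cohort, train_idx = split$train_idx)
fit    <- fit_mlp(mm, network_spec(seed = 1), split)
fit
#> <cce_mlp> 8-5-1 tanh perceptron, converged after 72 evaluations (loss 0.1213)
#> # A tibble: 2 × 7
#>   set      r2 r2_adj   mse   mae     n     p
#>   <chr> <dbl>  <dbl> <dbl> <dbl> <int> <int>
#> 1 train 0.758  0.757 0.243 0.393  1656     8
#> 2 test  0.768  0.757 0.269 0.411   184     8

sens <- restart_sensitivity(mm, network_spec(), n_restarts = 50, base_seed = 42)
sens
#> <sensitivity_result> mean Garson importance over 50 restarts
#>    length_of_stay  institution_type    insurance_type           surgery
#>            0.1949            0.1564            0.1341            0.1308
#>            gender institution_level  admission_season               age
#>            0.1234            0.1209            0.0895            0.0500
```

The held-out R² ≈ 0.77 says the network explains most of the log-scale
expenditure variance; the importance vector (sums to 1) recovers the
generator's ground-truth ordering — length of stay first, then institution
type, then insurance type. `autoplot(sens)` draws the ranking;
`sensitivity_checkpoints()` shows the importances stabilizing as restarts
accumulate.

A thin CLI over the same functions ships in `inst/cli/cce.R`
(`simulate`, `account`, `report`, `sensitivity` subcommands).

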