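# orscreen

High-throughput screens that match odorants to olfactory receptors (ORs)
produce hundreds of 96-well plates of dual-luciferase photon counts, from
which a handful of true receptor–ligand pairs must be distilled. `orscreen`
implements that distillation as a tested, reusable three-stage pipeline for
anyone analyzing (or re-analyzing) heterologous OR screening data:

1. **Primary screen** — firefly/Renilla normalization, per-plate
   standardization against on-plate Olfr544 standard wells
   (`s = mean(agonist) − mean(diluent)`, all ratios divided by `s`),
   subtraction of each receptor's no-odor baseline plate, and selection of
   the top 5% of receptor/odor pairs (≤ 10 ligands per receptor).
2. **Secondary screen** — one-way ANOVA across no-odor/1/10/100 µM
   triplicates; pairs advance at p < 0.05.
3. **Dose-response** — three-parameter logistic fit
   `y = bottom + (top − bottom) / (1 + 10^(logEC50 − x))` by multi-start
   Levenberg–Marquardt, and a composite agonist call requiring
   (i) non-overlapping 95% CIs of top and bottom, (ii) se(logEC50) < 1 log
   unit, and (iii) an extra sum-of-squares F test showing the receptor
   responds more than the matched empty-vector control.

Cross-stage ROC/AUC validation, readers/writers for the five tab-separated
screening data schemas (including the `9999` and `−12` no-odor sentinels),
and a ground-truthed synthetic screen generator emitting the same schemas
round out the package. See `vignettes/screening-methods.Rmd` for the model
and design decisions.

## Worked example

A simulated screen at the real study's run geometry (85 receptors × 11
odorants, twelve-plate runs, ~2% planted agonist pairs):

```r
library(orscreen)
cfg   <- sim_config(n_receptors = 85, n_odors = 11, agonist_density = 0.02)
truth <- sim_truth(cfg, seed = 42)
scr   <- simulate_primary_screen(cfg, truth, seed = 42)
hits  <- primary_screen_scores(scr$records)
sel   <- hits[hits$selected, c("receptor_id", "odor_id")]
sec   <- simulate_secondary(sel, truth = truth, seed = 43)
fwd   <- secondary_screen_results(sec)
dose  <- simulate_dose_response(fwd[fwd$passed, c("receptor_id", "odor_id")],
                                truth = truth, seed = 44)
res   <- run_screen_pipeline(scr$records, sec, dose)
res
#> screening pipeline result
#>   primary pairs scored:   935 (selected 46)
#>   secondary pairs tested: 46 (passed 23)
#>   dose-response calls:    23 (agonists 19)
#>   AUC primary -> secondary: 0.972
#>   AUC secondary -> agonist: 0.592
head(res$ec50, 4)
#> # A tibble: 4 × 3
#>   receptor_id odor_id reported_log_ec50
#>   <chr>       <chr>               <int>
#> 1 1011        3006                   -6
#> 2 1011        3010                   -6
#> 3 1023        3011                   -5
#> 4 1027        3007                   -5
```

935 pairs were scored (85 × 11); `floor(0.05 × 935) = 46` were selected;
23 showed a concentration effect; 19 passed all three agonist criteria —
against 22 planted true agonist pairs, with the reported integer log EC50s
(e.g. −6 ≙ 1 µM) matching the planted values. The primary→secondary AUC of
0.97 shows the ranking score strongly predicts the next stage.

A thin command-line interface over the same functions lives in
`exec/orscreen` (`simulate`, `validate`, `primary`, `secondary`, `dose`,
`run`).

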