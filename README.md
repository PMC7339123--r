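# bilayertools

Quantitative analysis of lipid-bilayer modification assays: how small
amphiphilic molecules (alkaloids, flavonoids, anesthetics) change membrane
interfacial electrostatics and lipid packing, and how those changes
regulate reconstituted ion channels.

The package implements the full analysis chain used in planar-bilayer and
liposome work, with a synthetic-data module that emulates every instrument
with known ground truth:

| Assay | Analysis | Key functions |
|---|---|---|
| Carrier-mediated conductance | boundary potential via the Boltzmann relation Δφ_b = (kT/e)·ln(G_m/G_m⁰); Langmuir fits Δφ(C) = Δφ(∞)·C/(C+K) | `boltzmann_delta_phi`, `fit_langmuir` |
| Ratiometric dye fluorescence | dipole-potential changes from dual-excitation ratios | `ratio_to_dipole_shift`, `dipole_calibration` |
| Differential scanning calorimetry | pre/main transition temperatures, half-widths, enthalpies, van't Hoff deconvolution, shifts vs control | `dsc_preprocess`, `dsc_features`, `dsc_deconvolve`, `dsc_shifts` |
| Calcein leakage | RF(t) = 100·(I−I₀)/(I_max/0.9−I₀), plateau RF_max | `compute_rf`, `estimate_rf_max` |
| Single-channel records | half-amplitude idealization, conductance (normal histogram fit), dwell times (truncated-exponential MLE), χ² acceptance, G(V), macroscopic I∞/I∞⁰ | `idealize`, `conductance_stats`, `dwell_stats`, `gv_curve`, `macroscopic_ratio` |
| Descriptor screening | Pearson r with Fisher-transform 90% CIs, Spearman confirmation | `pearson_fisher`, `spearman_rank`, `effect_descriptor_screen` |

`run_study()` orchestrates a complete synthetic study from one seeded JSON
configuration and reports recovered versus generating parameters.

## Worked example

```r
library(bilayertools)

# fit a Langmuir isotherm to a noisy strong-modifier adsorption series
s <- gen_adsorption_series(adsorption_model(118, 32, noise_sd = 2, seed = 7))
fit_langmuir(s)
#> Langmuir adsorption fit (nonlinear), compound 'synthetic'
#>   dphi(max) = 118.20 +/- 1.47 mV
#>   K         = 33.32 +/- 1.79 uM

# run a full three-compound synthetic study
report <- run_study(example_study_config(seed = 1))
report
#> Synthetic study report (seed 1 )
#>
#> Bilayer effects:
#>  compound dphi_b_max dphi_b_max_err k_uM k_err  k_na dphi_d_max ...
#>    strong     118.23          0.714 32.3 0.681 FALSE       91.7
#>  moderate      51.74          1.155 86.2 6.953 FALSE       39.3
#>  inactive       3.87          0.345   NA    NA  TRUE         NA
#>  ... neg_delta_t_m delta_t_half rf_max
#>           4.82         3.60      57.35
#>           2.90         0.90      31.31
#>          -0.00         0.00       2.11
#>
#> Channel effects:
#>  compound g_sc_before g_sc_after tau_before tau_after i_ratio
#>    strong        48.9       44.9      0.115    0.0764     4.1
#>  moderate        48.9       46.8      0.118    0.0615     0.3
#>  inactive        49.0       50.0      0.115    0.1276     1.0
```

Reading the output: the strong modifier's fitted maximal boundary-potential
reduction (118.2 mV) and desorption constant (32.3 µM) recover the
generating truth (118, 32); its main melting transition shifts down 4.8 °C
and broadens by 3.6 °C with the pretransition abolished; calcein leakage
plateaus at 57%; the channel's conductance drops from ~49 to ~45 pS with
the open dwell shortened from 115 ms to 76 ms; macroscopic pore-forming
activity rises 4.1-fold. The `inactive` compound's K is flagged `NA`
because a ~4 mV maximal effect is below the 10 mV detectability floor.

See `vignettes/bilayer-assays.Rmd` for the models, estimator choices,
fixture noise levels, and their rationale.

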