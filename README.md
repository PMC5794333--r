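# osmoquant

Quantification toolkit for studying osmoadaptation in halophilic
heterotrophic protists. Microorganisms in hypersaline habitats either let
salt in (and evolve acidic, salt-dependent proteomes) or keep it out,
balancing osmotic pressure with molar concentrations of *compatible
solutes* such as glycine betaine (GB) and ectoine (Ect). Deciding which
strategy an organism uses takes three quantitative measurements, and this
package implements all three as tested R code for the scientists who run
them:

* **Quantitative ¹H-NMR** — detect, assign and integrate compatible-solute
  peaks against an internal standard (TMSP), convert areas to tube
  molarity via
  `c_s = (A_s / A_std) · (n_std / n_s) · c_std`,
  and scale to intracellular molarity through a cylinder-plus-two-cones
  cell-volume model (`V_total = π(w/2)²L + 2·⅓π(w/2)²L`, in pl). Includes
  ¹³C-satellite analysis that splits labelled from unlabelled GB by the
  one-bond ¹³C–H coupling (J ≈ 144 Hz).
* **Corrected relative fluorescence (CRF) ion imaging** — three-stratum
  threshold segmentation of micrographs (background < cytoplasm <
  vacuole) and `CRF_C = I_C − A_C·I_B`, `CRF_norm = CRF_C / A_C`, the
  background-corrected per-pixel fluorescence of the cytoplasm.
* **Michaelis–Menten kinetics under salt/osmolyte stress** — nonlinear
  least-squares fits of `v = V_max·S/(K_m+S)` per condition, with the
  derived comparison metrics: specificity constant `V_max/K_m`, residual
  activity (% of reference `V_max`), osmolyte performance (% of reference
  `V_max/K_m`).

Around these sit the study's statistical layer (Welch's *t* from raw data
or summary triples, Pearson regression with R² and p, one-way ANOVA with
Tukey HSD, fold changes), seeded synthetic-data generators (spectra with
Lorentzian multiplets and ¹³C satellites, three-stratum phantom
micrographs, noisy rate series, growth counts) that give every pipeline
stage known ground truth, plain-text readers/writers (two-column and
JCAMP-DX spectra, PGM/TIFF/PNG images, CSV tables, YAML solute libraries),
a pipeline runner with reproducible run records, and a thin CLI
(`inst/scripts/osmoquant`).

## Worked example

Simulate a mixture spectrum with GB at 120 mM and Ect at 50 mM against a
500 mM TMSP standard, quantify it, and scale to intracellular molarity for
5×10⁴ cells of 8.01 pl in a 600 µl tube:

```r
library(osmoquant)
spec <- simulate_spectrum(c(GB = 0.12, Ect = 0.05), standard_conc = 0.5)
(q <- quantify(spec))
#> # A tibble: 3 × 5
#>   solute identified detected_shift   area tube_conc_mol_l
#>   <chr>  <lgl>               <dbl>  <dbl>           <dbl>
#> 1 Ch     FALSE               NA    0               0
#> 2 Ect    TRUE                 2.25 0.0815          0.0500
#> 3 GB     TRUE                 3.27 0.587           0.120
round(intracellular_concentration(q$tube_conc_mol_l, 600e-6, 5e4, 8.01), 2)
#> [1]   0.00  74.94 179.82
```

Choline is reported absent (all its reference peaks must match before it
counts as identified), and the generating 120/50 mM are recovered to three
digits; the intracellular column shows how strongly the per-cell volume
concentrates the tube signal. Kinetics work the same way — simulate or
load a rate table, fit, and compare conditions:

```r
d <- simulate_rate_data(kinetics_sim_config(0.163, 227, noise_cv = 0.02, seed = 4),
                        condition = "1.2 M NaCl", enzyme = "MDH")
(f <- fit_mm(d))
#> Michaelis-Menten fit [1.2 M NaCl]
#>   Km   = 0.1645 mM (se 0.00289)
#>   Vmax = 229.8 U/mg (se 1.04)
#>   Vmax/Km = 1397 U mg^-1 mM^-1, n = 24
round(residual_activity(f, list(km = 0.022, vmax = 1486)), 1)
#> [1] 15.5
```

`tidy()`, `glance()` and `autoplot()` methods expose fits in the usual
broom/ggplot2 shapes, and `demo_salinity_gradient()` runs the whole chain
(simulate spectra along a salinity gradient → quantify → scale →
regress on NaCl molarity) at desk scale.

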