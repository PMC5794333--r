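---
title: "Quantification methods for osmoadaptation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for osmoadaptation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoquant)
```

# Scope

Halophilic heterotrophic protists that follow the *salt-out* strategy keep
inorganic ions out of the cytoplasm and balance external osmotic pressure
with molar amounts of compatible solutes — small zwitterions such as glycine
betaine (GB) and ectoine (Ect). Demonstrating that strategy experimentally
rests on three quantitative procedures, each of which this package
implements as tested, reusable code:

1. **Internal-standard quantitative ¹H-NMR** of compatible solutes, scaled
   to intracellular molarity via a geometric cell-volume model, including
   resolution of ¹³C₂-labelled from unlabelled glycine betaine through
   satellite doublets;
2. **Corrected relative fluorescence (CRF)** ion imaging: three-stratum
   intensity segmentation of micrographs and background-corrected
   per-area fluorescence;
3. **Michaelis–Menten enzyme characterisation** under salt and osmolyte
   stress, with the derived comparison metrics (specificity constant,
   residual activity, osmolyte performance);

plus the small-sample statistical layer used around them (Welch's *t*,
Pearson regression, one-way ANOVA with Tukey HSD, fold changes), and
seeded synthetic-data generators that provide ground truth for every stage.

# Quantitative NMR

## Signal model

Spectra are modelled as sums of Lorentzian lines on a descending ppm axis.
Each reference peak of a solute at tube concentration $c$ with $n_H$
equivalent protons contributes total area proportional to $c \cdot n_H$;
multiplets split the area into binomially weighted lines (first-order
approximation) separated by $J/\nu_0$ ppm at spectrometer frequency
$\nu_0$ (MHz). Defaults: 400 MHz, 1.5 Hz full width at half maximum
(routine solution-state linewidth), 32768 points over $-0.5$ to 10 ppm
(about twelve samples per linewidth). No time-domain simulation, phase or
baseline artefacts are modelled: the generators emulate well-processed
spectra, so passing round trips demonstrate the correctness of the
quantification arithmetic, not robustness to bad shimming or phasing.

## Quantification

Concentration follows the internal-standard relation
$$c_s = \frac{A_s}{A_{std}} \cdot \frac{n_{std}}{n_s} \cdot c_{std},$$
with one designated quantification peak per solute (GB: the 9-proton
trimethylammonium singlet at 3.27 ppm; Ect: the methyl resonance; TMSP as
the 9-proton standard at 0.0 ppm). The proton-count ratio is what makes
the result molar; it is stated explicitly and tested rather than folded
into an opaque calibration factor.

Peak detection takes local maxima above `min_snr` (default 3) times a
robust noise estimate (median absolute deviation over a signal-free region,
default 9–10 ppm), excluding the residual-HOD window 4.6–4.9 ppm.
Assignment matches each reference peak to the nearest detected peak within
`tol` (default 0.03 ppm), greedily by distance with ties broken toward
lower ppm; a solute counts as identified only when *all* its reference
peaks match, so a lone coincidental line is never reported as a solute.

## Integration window and baseline

Areas are trapezoidal integrals over `center ± window` after subtracting a
linear baseline anchored at the window edges. Two defaults here deserve
justification because they drive the error budget:

* **Window half-width 0.004 ppm** (1.6 Hz at 400 MHz, about one
  linewidth). The default solute library contains GB at 3.27 ppm and an
  Ect methylene at 3.29 ppm — 0.02 ppm apart. Any window wide enough to
  capture most of a Lorentzian (tails decay as $1/x^2$) swallows the
  neighbour: a ±0.05 ppm window takes up essentially the whole 3.29 ppm
  peak into the GB integral (a ~20% error at equimolar GB/Ect). A narrow
  window keeps cross-talk below 1% even at 15:1 concentration ratios. The
  price — only ~72% of each line's analytic area is captured — cancels
  exactly in the ratio to the internal standard, because every peak shares
  the window and the linewidth.
* **Baseline flanks.** A baseline anchored at two *single* noisy samples
  injects variance $\propto (2w)^2\sigma^2/2$ into the area, which at
  realistic noise dominates every other error source. `quantify()`
  therefore averages the baseline level over a short flank (default half a
  window) outside each edge; `integrate_peak()` keeps the bare-endpoint
  behaviour as its default so the primitive stays simple and predictable.

## Label analysis

In 1,2-¹³C₂-glycine betaine the one-bond ¹³C–H coupling (default
$J = 144$ Hz, configurable) splits the affected resonances into symmetric
satellite doublets at $\pm J/2\nu_0$ ppm about the parent shift, with total
area equal to the unlabelled singlet at the same concentration (label
conservation, tested). `label_ratio()` integrates the central singlet
(unlabelled GB), both satellites (labelled GB) and the Ect quantification
peak with one common window (default ±0.006 ppm) so capture fractions
cancel across the three components, corrects each for proton count, and
normalises to the smallest nonzero component. At 400 MHz and
$J = 144$ Hz the high-field satellite (3.45 ppm) lies 0.01 ppm from Ect's
3.44 ppm methylene — a further reason the windows must stay narrow. If
$J/2\nu_0$ does not clear twice the window, satellites are unresolvable
from the central peak and the function refuses with a diagnostic rather
than returning a biased split.

## Intracellular scaling

Tube concentration times sample volume gives moles; dividing by (cell
count × mean single-cell volume) gives intracellular molarity. The cell
volume uses the published cylinder-plus-two-cones model
$$V_{cyl} = \pi (w/2)^2 L, \qquad V_{2cones} = 2\cdot\tfrac13 \pi (w/2)^2 L,$$
summed and reported in picolitres. The formulas are implemented verbatim,
including their geometric oddity that the cones stand on the full average
length (so total $= \tfrac53 V_{cyl}$, which the tests assert as a guard
against silent "fixes"). Measured cell height does not enter the printed
model and is ignored. Salinity in % w/v converts to molarity as
$10 \cdot \text{percent} / 58.44$ g/mol; this reproduces the published
19% → 3.25 and 21% → 3.59 mol/l conversions exactly, while 5% gives
0.856 → 0.86 against a published 0.85 — documented, not adjusted.

# Ion imaging

Pixels are classified background / cytoplasm / vacuole by two intensity
thresholds ($I \le t_{low}$, $t_{low} < I \le t_{high}$, $I > t_{high}$),
reflecting the stratum ordering $I_B < I_C < I_V$. When thresholds are not
given they are chosen by two-threshold between-class variance maximisation
(three-class Otsu on a 256-bin histogram) — the original analysis set
thresholds by eye in an image program, so automatic selection is this
package's choice and manual thresholds remain first-class. A uniform image
has no separable strata and is an error, as is an empty cytoplasm stratum.

The corrected relative fluorescence takes $I_C$ as the *summed* cytoplasm
intensity (vacuole pixels excluded):
$$CRF_C = I_C - A_C \cdot I_B, \qquad CRF_{norm} = CRF_C / A_C,$$
with $I_B$ the equal-weight mean of four background regions (default: four
corner squares of 1/16 image width). Reading $I_C$ as a mean would make
the $A_C \cdot I_B$ subtraction dimensionally inconsistent with the later
normalisation, so the summed reading is used. $CRF_C$ may legitimately be
negative for dim cells and is reported as computed. On noise-free phantoms
$CRF_{norm}$ equals the cytoplasm-minus-background level difference
exactly; shift invariance and scale equivariance hold to machine precision
and are tested. Vacuole area and mean intensity are reported alongside but
never enter the CRF.

The synthetic phantom is an elliptical cell with a circular vacuole on a
flat background plus clipped Gaussian noise. It deliberately omits
illumination gradients, out-of-focus light and cell-shape irregularity;
segmentation accuracy on real micrographs is therefore not certified by
these tests, only the correctness of the CRF arithmetic given a
segmentation.

# Enzyme kinetics

Initial rates come from absorbance-at-340-nm traces via Beer–Lambert
($\varepsilon = 6220$ M⁻¹cm⁻¹ for NADH, 1 cm path — standard values),
converted to specific activity in U mg⁻¹ (1 U = 1 µmol min⁻¹). The
Michaelis–Menten fit minimises
$\sum_i (v_i - V_{max} S_i/(K_m+S_i))^2$ by constrained nonlinear least
squares (`nls`, port algorithm, positive bounds; Levenberg–Marquardt as
fallback), started from a Hanes–Woolf linearisation ($S/v$ on $S$).
Unweighted by default — no error model is assumed — with optional $1/v$
weighting. A fit needs at least three distinct substrate levels, and a
fitted $K_m$ beyond 100× the largest substrate concentration is rejected
as unidentified (the plateau was never approached). Derived metrics are
plain arithmetic on the fits: specificity constant $V_{max}/K_m$, residual
activity $100\, V_{max}/V_{max}^{ref}$, osmolyte performance
$100\,(V_{max}/K_m)/(V_{max}/K_m)^{ref}$; they accept fitted objects or
printed parameter tables interchangeably. Substrate for ICDH is treated as
total DL-isocitrate, matching how the reference $K_m$ values are quoted.
Substrate inhibition and allosteric models are out of scope — the
reference data were fitted hyperbolically and so are these.

Parameter recovery is validated over all sixteen published ($K_m$,
$V_{max}$) pairs: 8 substrate levels spanning 0.2–20 × $K_m$
(geometric), triplicates, 2% multiplicative noise, 200 seeds per pair;
the worst per-pair median relative error stays under 5% for both
parameters (typically under 2%).

# Statistics

The statistical layer mirrors the analyses the quantification feeds:
Welch's unequal-variance *t* (from raw samples or from (mean, sd, *n*)
summaries — identical formulas, so published summary tables can be tested
directly), ordinary least squares with $R^2$ as squared Pearson
correlation, the classic one-way ANOVA decomposition, and Tukey–Kramer
HSD via the studentized range distribution. Test statistics are computed
from their defining formulas in this package; tail probabilities come from
R's numerically integrated distribution functions (`pt`, `pf`, `ptukey`),
and the test suite cross-checks every p-value against the independent
implementations in `t.test`, `aov` and `TukeyHSD` to 10⁻⁶, plus a
10,000-simulation null calibration of the Welch test (rejection rate at
$\alpha = 0.05$ required to land in [0.04, 0.06]). All tests are
two-sided at $\alpha = 0.05$. Shapiro–Wilk and Bartlett pre-tests, used
upstream only as gatekeepers, are not reimplemented; `stats` provides
them.

Regression against salinity is run on per-salinity *means* by default
(matching how such results are plotted and reported); replicate-level
regression is available by passing the per-replicate table directly.

# Synthetic-data generators

The generators' defaults are the study conditions, not tuning knobs:

* spectra at 400 MHz, 1.5 Hz linewidth, TMSP standard at 0.5 mol/l;
* growth arms at the published endpoint means (control 280, GB 983,
  Ect 1380, Ch 3247 cells/ml), triplicate counts; the single
  `sd_fraction = 0.3` is a mid-range stand-in for very unequal published
  dispersions (CVs 0.03–0.65);
* kinetics at the published Table parameters with `noise_cv = 0.02`, a
  stand-in since no replicate scatter is reported for the rate data;
* phantoms with strata 10/50/120 on a 96×96 frame.

Every generator is deterministic under its `seed` and leaves the caller's
RNG stream untouched. Noise models (additive Gaussian on spectra,
clipped Gaussian on pixels, multiplicative Gaussian on rates) are
plausible conventions; no acquisition noise figures exist to infer from.

The validation studies use these problem sizes: 50 random mixtures per
round-trip arm, 200 seeds per kinetic parameter pair, 10,000 null
simulations for the Welch calibration — sizes at which the Monte-Carlo
error of each summary is comfortably below the tolerance it is checked
against.

**Concentration regimes in the NMR round trip.** The noise-free arm draws
mixtures across a wide dynamic range (0.02–0.3 mol/l against the 0.5 mol/l
standard) and requires recovery within 2% — this stresses integration bias
(neighbour-peak cross-talk, baseline curvature). The noisy arm (noise sd =
1% of the spectrum's maximum height) draws mixtures at 0.25–0.5 mol/l, the
molar regime a salt-out halophile actually accumulates, and requires 10%
recovery in at least 95% of cases. The split is deliberate: with the noise
pinned to the *global* maximum (the 500 mM standard peak), a 0.02 mol/l
3-proton peak carries less information than any unbiased area estimator
can recover at 10% — the matched-filter bound on the area standard
deviation already exceeds that tolerance — so demanding it would test
arithmetic against an information-theoretic wall rather than against the
implementation.

# Degenerate inputs and numerical conventions

* Flat spectra detect no peaks (empty result, not an error); a missing
  internal standard is an error because nothing can be quantified.
* Solutes not identified quantify to 0 mol/l rather than NA: absence of
  all reference peaks is evidence of absence at the detection limit.
* Areas are floored at 0 after baseline subtraction.
* Assignment is deterministic and invariant to peak input order; ties in
  the greedy matching break toward lower ppm.
* `welch_t` on two zero-variance groups with equal means returns
  $t = 0, p = 1$ by convention; with unequal means it is an error.
* Group standard deviations are reported as `NA` for single-cell groups
  (undefined), never as 0.
* Single-precision display rounding never enters comparisons; tests use
  explicit tolerances.

# Open choices

* Published shift tables disagree on ectoine's methyl resonance (2.25 vs
  2.44 ppm); the library carries both, quantifies at 2.25 ppm by default,
  and `solute_library(ect_quant = "2.44")` switches. Neither is declared
  "correct".
* The 500 mM TMSP standard concentration is unusually high for a shift
  reference but is treated as a plain parameter, overridable in
  `internal_standard()`.
* Whether reference analyses integrated single lines or summed multiplets
  is unknown; this package integrates the designated quantification line.
* The background regions' exact shape and placement are unknown upstream;
  corner squares are the default and any four rectangles can be supplied.

# Limitations

Real spectra bring phase errors, baseline roll, solvent suppression
artefacts and second-order multiplets; real micrographs bring uneven
illumination and debris; real rate assays bring substrate depletion within
the measurement window. None of these are simulated, so green tests here
certify the analysis arithmetic and its documented error budget — they do
not certify performance on degraded raw data.
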