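# hemoforce

Quantification of left-ventricular (LV) hemodynamic forces from
time-resolved three-directional (4D flow) MRI velocity data, aimed at
researchers studying diastolic mechanical dyssynchrony — e.g. in heart
failure with left bundle branch block — from intraventricular flow.

## What it computes

Inside the segmented LV blood pool the pressure gradient follows from the
Navier–Stokes momentum balance (body forces excluded),

∇p = −ρ ∂v/∂t − ρ (v·∇)v + μ ∇²v,

with ρ = 1060 kg/m³ and μ = 0.004 N·s/m² for blood. Integrating ∇p over
the lumen volume at every time frame yields the hemodynamic force vector
F(t) — the net force exchanged between the blood pool and the myocardial
walls. F(t) is projected onto the anatomical long axis (apex → base) and
short axis (anteroseptal → inferolateral), and the directional
heterogeneity of filling is summarized per phase window by

* the **SAx/LAx peak-force ratio**: max |F·ŝ| / max |F·l̂| (maxima searched
  independently within the window), and
* the **SAx/LAx RMS-force ratio**: rms(F·ŝ) / rms(F·l̂),

evaluated over full diastole and the E- and A-wave windows separately. A
synchronously filling ventricle keeps these ratios small; dyssynchronous
relaxation tilts the early-filling force off-axis and drives them up.

The package also provides the surrounding pipeline: phase-contrast
background correction (degree-4 polynomial over static tissue), temporal
phase unwrapping, mask re-timing, inflow/outflow QC (15% discrepancy
gate), E/A-wave detection from valve-probe speed curves, a cohort
statistics battery (Lilliefors-gated t/Wilcoxon comparisons, regressions
on QRS duration and septal–lateral delay), and a synthetic-data generator
with analytic phantoms whose pressure gradients are known in closed form.

## Worked example

A noise-free LV filling phantom whose early inflow jet is tilted 45° off
the long axis (the dyssynchrony surrogate), run through the full pipeline:

```r
library(hemoforce)
ph  <- genLVPhantom(phantomSpec(kind = "lv_filling", eJetAngle = 45))
ph$mask
#> Mask4D: 32 x 32 x 48 voxels, 40 frames
#>   lumen volume 63.7 .. 98.9 ml
row <- runSubject(ph$flow, ph$mask, ph$landmarks,
                  unwrap = FALSE, backgroundCorrect = FALSE)
attr(row, "phases")
#> CardiacPhases: systole [3, 13] diastole [14, 40] | E [20, 30] A [33, 40]
row[, c("ratio_max_E", "ratio_max_A", "ratio_rms_full", "e_defined")]
#>  ratio_max_E  ratio_max_A ratio_rms_full e_defined
#>            1 4.862972e-17       0.233926      TRUE
```

The E-wave ratio is 1 — the early-filling force is tilted 45°, so its
short- and long-axis peak components are equal (tan 45°) — while the
on-axis A-wave jet leaves the late ratio at zero. Published summary tables
can be re-analyzed directly; the septal–lateral mechanical delay summaries
(57.6 ± 62.0 ms, n = 9 vs −4.4 ± 54.9 ms, n = 9) give:

```r
ttestFromSummary(57.6, 62.0, 9, -4.4, 54.9, 9)
#> pooled-t: statistic = 2.246, df = 16, p = 0.03918
```

`genCohort()` + `runSubject()` + `runCohort()` chain the same pieces into
a two-group in-silico study with QRS coupling; see the vignette
(`vignettes/hemodynamic-forces.Rmd`) for the model, the numerical scheme,
parameter defaults and the generator's scope and limits.

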