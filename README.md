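# strobomech

Stroboscopic optical mechanotyping of adherent cells: recover per-pixel
maps of the complex dynamic shear modulus — storage modulus G′ (elastic)
and loss modulus G″ (viscous) — for every cell in a field of view from a
single ultrasonic burst experiment, and compare cell populations
statistically. The package is aimed at cell-mechanics labs analysing
stroboscopic phase-contrast movies of acoustically sheared cultures, and
it ships a full synthetic-experiment generator so the entire analysis
chain can be verified by parameter recovery without hardware.

## Method in brief

Cells adhering to a dish sit in an oscillating fluid flow at carrier
frequency f₀ (tens of kHz). Non-fluorescent tracer beads (radius R_b) on
the dish floor trace the flow; the wall shear stress is the
linear-gradient estimate

    σ̃_k = μ ũ_k(z = R_b) / R_b ,      k ∈ {x, y}

with ũ_k the homodyne *velocity* phasor from particle tracking. Cell
motion maps δ̃_k come from block-matching digital image correlation (5×5
px comparison boxes, 2.57 µm) against a rest reference image, homodyned
at f₀. Spatial gradients give the pure and simple shear strains

    γ̃_p = ∂δ̃_x/∂x + ∂δ̃_y/∂y ,      γ̃_s = ∂δ̃_x/∂y + ∂δ̃_y/∂x

and the modulus follows from the compliance sums

    1/G̃_p = (1/σ̃_x) ∂δ̃_x/∂x + (1/σ̃_y) ∂δ̃_y/∂y
    1/G̃_s = (1/σ̃_x) ∂δ̃_x/∂y + (1/σ̃_y) ∂δ̃_y/∂x
    G̃ = (G̃_p + G̃_s)/2 = G′ + iG″ .

Acquisition is stroboscopic: frames are taken at
f_strob = N/(N+1)·f_repet, one per pulse, so the reconstructed time base
has spacing δt = 1/(N·f_repet) and resolves the ultrasonic motion at full
field of view. Homodyne (lock-in) detection of every time series rejects
all off-carrier noise. The methods vignette
(`vignettes/stroboscopic-mechanotyping.Rmd`) details the conventions,
parameters and the error budget.

## Worked example

Simulate a two-population co-culture (soft "green" cells, median |G̃| 4.4
kPa; stiff "orange" cells, 6.3 kPa) and analyse it end to end:

```r
library(strobomech)
scene <- two_population_scene(seed = 1)
sim   <- simulate_experiment(scene)          # renders the image stacks
run   <- run_pipeline(sim, mechanotype_config(search_radius = 6))
print(run)
```

```
Stroboscopic mechanotyping run
  segmentation ok (0.8s)
  tracking     ok (9.7s)
  dic          ok (31.2s)
  mechanics    ok (0.0s)
  statistics   ok (0.1s)
  validation   ok (0.1s)
  green    median |G| = 4.56 kPa (mean 4.64, n = 205 boxes)
  orange   median |G| = 6.66 kPa (mean 7.31, n = 220 boxes)
  Mann-Whitney |G| p = 2.79e-39
Error budget (relative):
  flow / stress       : 0.2%
  strain noise floor  : 8.8%
  modulus (propagated): 8.8%
  systematic stress bound (depth of field): 58%
```

Reading the output: both population medians are recovered within a few
percent of the generated ground truth (4.4 / 6.3 kPa), the soft/stiff
ordering is preserved, and the Mann–Whitney U test separates the
populations decisively (p ≪ 0.001) using the DIC-box as the statistical
unit. The error budget reports the flow-field self-consistency residual,
the strain noise floor measured in a blank (cell- and tracer-free)
region, their quadrature combination, and the depth-of-field bound on the
systematic stress error. `summary(run)` returns the per-group summary
table, `plot(run, "modulus")`, `plot(run, "ratio")` and
`plot(run, "boxplot")` show the |G̃| map, the log₁₀(G′/G″) map and the
population box plot, and `write_run_report(run, dir)` writes the box
table (CSV), maps (TIFF) and a JSON report.

A thin command-line front end over the same functions lives at
`inst/cli/strobomech` (subcommands `simulate`, `run`, `stats`).

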