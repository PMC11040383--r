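---
title: "Stroboscopic optical mechanotyping: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroboscopic optical mechanotyping: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(strobomech)
```

## The measurement principle

Adherent cells in a dish are sheared by an oscillating fluid flow driven by
an acoustic transducer: Gaussian-windowed bursts at a carrier frequency
$f_0$ (30 or 45 kHz) are repeated $N$ times at a rate $f_\mathrm{repet}$,
each burst `exp(-alpha^2 (t - t0)^2) sin(2 pi f0 t)` centred in its
repetition period ($t_0 = 1/(2 f_\mathrm{repet})$). The flow exerts a
viscous wall shear stress on the cells; the cells' micro-oscillations are
imaged stroboscopically and converted, box by box, into a complex dynamic
shear modulus
$$\tilde G = \tilde\sigma^H / \tilde\gamma^H = G' + i G'',$$
the frequency-domain ratio of shear stress to shear strain, whose real part
$G'$ (storage modulus) is the elastic response and imaginary part $G''$
(loss modulus) the viscous one.

Three ideas carry the method:

1. **Stroboscopic sampling.** The camera runs at
   $f_\mathrm{strob} = \frac{N}{N+1} f_\mathrm{repet}$, one frame per
   pulse, so successive frames step through the oscillation phase by a
   constant reconstructed interval
   $\delta t = 1/f_\mathrm{strob} - 1/f_\mathrm{repet} = 1/(N
   f_\mathrm{repet})$. The ultrasonic motion is thereby aliased onto a
   time base whose effective rate $N f_\mathrm{repet}$ comfortably
   oversamples the carrier (1 MHz for $N = 1000$, $f_\mathrm{repet} = 1$
   kHz), with a large field of view retained.
2. **Homodyne (lock-in) detection.** Every time series — bead
   displacements, DIC box displacements — is projected onto the single
   discrete-frequency bin nearest $f_0$. All off-carrier noise is
   rejected; the amplitude-estimate SNR improves by roughly
   $\sqrt{N/2}$ over reading the raw trace, which
   [`homodyne_snr_gain()`] quantifies by Monte Carlo (raw estimator: half
   the peak-to-peak excursion; SNR defined as truth/RMSE).
3. **Stress from tracer beads, strain from the cells.** Polystyrene beads
   (radius $R_b = 1.5\ \mu m$) resting on the dish trace the fluid motion;
   the wall stress is the linear-gradient estimate
   $\tilde\sigma_k = \mu\, \tilde u_k(z = R_b) / R_b$. Cell motion maps
   come from block-matching DIC against a rest reference image; their
   spatial gradients give the pure and simple shear strains
   $\tilde\gamma_p = \partial_x\tilde\delta_x + \partial_y\tilde\delta_y$
   and
   $\tilde\gamma_s = \partial_y\tilde\delta_x + \partial_x\tilde\delta_y$,
   and the compliances
   $$1/\tilde G_p = \tilde\sigma_x^{-1}\partial_x\tilde\delta_x +
     \tilde\sigma_y^{-1}\partial_y\tilde\delta_y,\qquad
     1/\tilde G_s = \tilde\sigma_x^{-1}\partial_y\tilde\delta_x +
     \tilde\sigma_y^{-1}\partial_x\tilde\delta_y,$$
   combined as $\tilde G = (\tilde G_p + \tilde G_s)/2$.

Note on nomenclature: the quantity called *pure shear* here,
$\partial_x\tilde\delta_x + \partial_y\tilde\delta_y$, is in standard
continuum terms the planar divergence (pure shear is conventionally the
difference of the diagonal gradients). The formulas above are implemented
exactly as written; only the naming is flagged.

## Phasor and sign conventions

All phasors are defined against $e^{+2\pi i f_0 t}$ evolution and
extracted with the analysis kernel $c = \frac{2}{N}\sum_n x_n e^{-2\pi i
f_0 t_n}$, so a cosine of amplitude $A$ returns $A$ at phase 0 and a sine
returns phase $-\pi/2$. Two consequences matter:

* **Stress is built from the velocity phasor.** The beads are tracked in
  *displacement*; the stress law needs the velocity gradient, so the bead
  displacement phasor is multiplied by $i\,2\pi f_0$ before entering
  $\tilde\sigma_k = \mu \tilde u_k / R_b$ (dimensional analysis:
  $\mathrm{Pa} = \mathrm{Pa\,s}\cdot(\mathrm{m/s})/\mathrm{m}$). Cell
  strain, by contrast, enters the compliance sums as the *displacement*
  gradient directly: an elastic cell strains in phase with the stress and
  yields a real $\tilde G$, a viscous cell lags by $\pi/2$ and yields
  $G'' > 0$. This velocity/displacement pairing is the only reading that
  keeps $\tilde G$ in pascal and makes the purely viscous synthetic case
  come out purely imaginary, which the unit tests verify. A
  `phasor = "displacement"` switch in `homodyne_flow()` retains the
  literal displacement-based reading of the stress law for sensitivity
  checks (it rescales all moduli by $2\pi f_0$ and rotates phases by
  $\pi/2$; it is not the default for the reasons above).
* **Common factors cancel in the ratio.** The Gaussian pulse envelope
  multiplies bead and cell motion alike; the homodyne coefficient of an
  envelope-modulated tone is the tone's phasor scaled by the record-mean
  envelope. Because stress and strain carry the same factor, it cancels
  in $\tilde G$ — the pipeline needs no envelope deconvolution. The same
  cancellation removes any common phase offset of the drive.

## Analysis parameters

| parameter | default | meaning |
|---|---|---|
| `box_size` | 5 px | DIC comparison box; 2.57 µm at 0.514 µm/px, the spatial resolution and the statistical unit |
| `search_radius` | 10 px | DIC integer search range; set it just above the expected peak displacement |
| `min_contrast` | 0.01 | intensity SD below which a box is textureless and flagged invalid (invalid boxes are excluded, never interpolated) |
| `stress_threshold` | 0.1 | a stress component enters a compliance sum only if its magnitude exceeds this fraction of the larger component; with one component excluded the remaining term alone defines $1/\tilde G$ (no factor-2 rescaling) |
| `min_per_cell` | 5 | minimum complete bead tracks per sub-FOV; the grid order $n$ is the largest value satisfying it |
| `mu` | 1.0e-3 Pa s | medium viscosity (water, room temperature) |
| `R_b_um` | 1.5 µm | tracer bead radius |
| `blur_sigma_frac` | 1/8 | segmentation background blur: a Gaussian whose ±2σ support spans half the smaller image dimension |

Numerical choices worth knowing:

* **DIC sub-pixel refinement.** After the integer normalized
  cross-correlation peak, displacements are refined by an iterative
  Gauss–Newton (Lucas–Kanade) fit of the intensity model, with a
  quadratic (log-parabola) peak fit as initialization fallback. The
  three-point parabola alone exhibits pixel locking whose per-box
  transfer slope varies by ~10%; since the modulus depends on *gradients*
  of the homodyne displacement, that locking would bias $|\tilde G|$
  upward by 15–25%. The intensity-model refinement removes it (per-box
  error ~0.03 px).
* **Quadratic flow interpolation.** Sub-FOV velocity phasors sit at the
  $n\times n$ cell centres; the per-pixel field is an order-2 tensor
  Lagrange interpolant through the nearest 3 nodes per axis, exact at the
  nodes, clamped to the boundary value outside the node hull.
* **Strains** are central differences on the box grid, one-sided at the
  borders; NA (invalid) boxes poison their stencil rather than being
  filled in.
* **DIC-box labelling.** A box joins a population only if the window
  spanning its own footprint *and its neighbour boxes* lies inside the
  (overlap-removed) channel mask. Requiring only the box footprint would
  let central differences straddle the cell boundary, where the
  cell/dish displacement discontinuity masquerades as strain.
* **Degenerate inputs.** Boxes with both stress components under the
  threshold, textureless boxes, and empty masks are flagged, not guessed;
  `segment_channel()` returns an empty mask when Otsu's threshold does
  not separate two genuinely distinct classes (guard: foreground mean at
  least 4 background-SDs above background), so pure-noise channels do not
  produce random half-splits.

## The synthetic experiment

`two_population_scene()` + `simulate_experiment()` constitute the forward
model against which the whole chain is verified by parameter recovery:

* Two cell populations ("green" soft, "orange" stiff) as elliptical
  patches of band-passed speckle (phase-contrast-like local contrast,
  cell contrast 0.12, dish background 0.06 on a 0..1 scale, camera noise
  0.005). Per-cell $|G|$ is lognormal (sdlog 0.25) rescaled so the
  realized population medians equal 4.4 and 6.3 kPa exactly; the loss
  angle is $\pi/4 \pm 0.15$ (storage and loss moduli comparable, as
  observed for these cell types).
* A spatially uniform velocity phasor of 1 m/s magnitude at the bead
  height (the measured order of magnitude), giving ~670 Pa stress and
  strains of a few percent.
* Ground-truth displacement fields constructed per cell so that the
  compliance relations above invert to the prescribed modulus *exactly*
  (affine fields for uniform cells; integrated local compliance for
  soft-centred cells). The oracle test applies the analysis operators to
  the noise-free field and recovers every cell's modulus to $10^{-6}$
  relative.
* Rendering: the rest texture is warped per frame by
  $\mathrm{Re}[\tilde\delta e^{2\pi i f_0 t_n}]$ times the in-period
  pulse envelope, using Catmull–Rom bicubic resampling (bilinear
  resampling leaves interpolation artifacts of ~0.06 px that dominate the
  strain noise floor); beads are drawn as anti-aliased dark discs
  advected by the fluid; the trailing $N_{aq} - N$ frames are at rest.
  Rendering is bit-reproducible given the scene seed.

What the generator does **not** emulate: optical point-spread functions,
depth-of-field effects (the model is purely 2-D; the systematic
stress-error bound `depth_of_field_bias()` is reported, not simulated),
acoustic wave propagation (the flow is prescribed, not solved), bead
inertia or sedimentation, illumination flicker, and mechanical coupling
between neighbouring cells. Passing recovery tests therefore demonstrate
the correctness of the *analysis chain* under the stated noise model, not
the hardware's systematics.

## Problem sizes

The default verification scene is 320×320 px with 8 cells per population
and $N = 250$ pulses ($N_{aq} = 375$ frames) — a scaled-down sibling of a
full experiment (512×512 px, ~70 cells, $N = 1000$): enough boxes
(~200 per population) for decisive statistics while a complete
render-and-analyse cycle stays under two minutes on one CPU. The homodyne
SNR demonstration uses $N = 1000$ samples, where the lock-in gain is
$\approx\sqrt{N/2} \approx 22$ over an ideal per-sample reading and
larger still over a peak-to-peak reading. All physical parameters (pixel
pitch, bead radius, viscosity, carrier and repetition frequencies,
population medians) are the experimental ones.

## Error budget

The validation stage reproduces the method's own error accounting:

* **Flow/stress error**: RMS residual between each complete track's own
  homodyne phasor and the interpolated field at its position, relative to
  the RMS field (`flow_residuals()`). With a uniform synthetic flow this
  is well under 1%; in a real, spatially varying flow it was the dominant
  term (~30%).
* **Strain noise floor**: median homodyne strain in a blank region (no
  cells, no tracers — the static dish) over the median strain in
  cell-labelled boxes (`blank_strain_noise()`): ~9% at default noise,
  same order as the ~5% observed on real data.
* **Modulus error**: the two combine in quadrature
  (`propagate_errors()`); with the real-data components 30% and 5% this
  is 30.4% — "of the order of 30%".
* **Systematic stress bound**: tracers anywhere within the ±0.87 µm depth
  of field may sit off the assumed $z = R_b$, bounding the relative
  stress bias by $0.87/1.5 \approx 58\%$ ("order of 60%"); sedimentation
  mitigates it in practice.

## DIC-box versus cell-based statistics

The DIC-box is the statistical unit throughout (global cell masking
only); `compare_box_cell_stats()` aggregates the same boxes per cell and
compares the two distributions. On synthetic scenes the group means agree
within the combined SEM of the difference and a Mann–Whitney test does
not separate them — the box-based shortcut loses nothing while avoiding
error-prone per-cell segmentation. Population comparisons use two-sided
Mann–Whitney U tests (distributions are non-normal by Shapiro–Wilk);
outliers beyond 1.5 IQR are excluded from box plots only, never from
tests. No multiple-testing correction is applied by default (one pairwise
comparison per experiment); a Holm option exists for multi-group designs.

## Known limitations

* The affine fluorescence/fast-camera registration is a configuration
  input, not estimated from the data.
* Cell-instance labels (for cell-based statistics) come from the
  generator or a user-supplied label image; instance segmentation is not
  automated.
* Stiff, weakly strained cells sit closer to the strain noise floor; their
  recovered moduli scatter more and can be biased a few percent downward
  by noise in the compliance denominator.
* The soft-centre construction integrates the local compliance along the
  axes; its inversion is exact only in the uniform-cell limit, so
  radial-gradient scenes validate trends (edge profiles), not third-digit
  recovery.

## A worked run

```{r, eval = FALSE}
scene <- two_population_scene(seed = 42)
sim <- simulate_experiment(scene)
run <- run_pipeline(sim, mechanotype_config(search_radius = 6))
print(run)
summary(run)
plot(run, "boxplot")
write_run_report(run, "results/run42")
```

`scripts/acceptance.R` wraps exactly this (plus the SNR and error-budget
anchors) and writes the headline numbers as JSON.
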