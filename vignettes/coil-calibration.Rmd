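---
title: "Calibrating magnetometer arrays with coil fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating magnetometer arrays with coil fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilcal)
```

## The estimation problem

On-scalp MEG with optically pumped magnetometers (OPMs) needs each
channel's gain $g$ (V/T), position $\mathbf r$ and orientation
$\mathbf n$ in a common frame. `coilcal` estimates them magnetically: the
sensor's response to the field of coil $i$ is modelled as

$$ b_i = g\, \mathbf B_i(\mathbf r) \cdot \mathbf n, $$

and the parameters minimize the sum of squared errors
$\sum_i (y_i - g \mathbf B_i(\mathbf r)\cdot\mathbf n)^2$ against the
measured response amplitudes $y_i$. Everything else in the package exists
to make this optimization well-posed and well-initialized: a continuous,
physics-constrained representation of each $\mathbf B_i$, a way to drive
the coils so that the first guess is a linear solve, and a simulator that
provides ground truth to score against.

## Field models: a real vector-spherical-harmonic basis

Inside a source-free sphere, each coil field is expanded as
$\mathbf B(\mathbf r) = \sum_{l=1}^{l_\max}\sum_{m=-l}^{l}
\beta_{lm}\, \mathbf w_{lm}(\mathbf r)$ with
$\mathbf w_{lm} = \nabla\!\left(r^l Y_{lm}(\theta,\varphi)\right)$, the
gradients of real regular solid harmonics. These fields are divergence-
and curl-free by construction, which is exactly the constraint Maxwell's
equations impose in the sensor volume and what gives the basis its noise
robustness: degree $l=1$ spans the three homogeneous components, $l=2$
the five independent first-order gradients, and degree $l$ contributes
$2l+1$ components ($l_\max = 5$ gives 35).

Conventions, fixed once and used everywhere:

* real $Y_{lm}$, orthonormal on the unit sphere, **no Condon–Shortley
  phase**; $\theta$ is the polar angle from $+z$, $\varphi$ the azimuth
  from $+x$;
* component ordering is degree-major, $l$ ascending with $m = -l \dots l$;
* each basis field is rescaled to **unit RMS magnitude on a reference
  sphere** of radius $R_0 = 0.1$ m (configurable). Any fixed
  per-component rescaling cancels in every estimator in the package (the
  coefficient fit, the current synthesis and the two linear solves are
  all pseudo-inverse solves that absorb column scalings consistently), so
  we chose a convention that is easy to state and to reproduce rather
  than any particular library's normalization. The basis-invariance is
  verified by a test that refits all models on a different $R_0$ and
  checks the sensor estimates do not move.

Internally each $r^l Y_{lm}$ — a homogeneous polynomial of degree $l$ —
is expanded exactly in the monomial basis (solved once per $l_\max$ by
projection at generic sample points, cached), so fields and their exact
Jacobians are evaluated by monomial calculus. This avoids the
$1/\sin\theta$ singularities of spherical-component formulas on the $z$
axis, where mapping or sensor positions may legitimately lie.

Coefficients are fitted by $\boldsymbol\beta = S^{+}\mathbf m$ with an
SVD pseudo-inverse (relative singular-value cutoff $10^{-10}$,
configurable); the design matrix $S$ holds the basis fields at the
measurement points, either as all three Cartesian components (triaxial
rows, the default) or projected on single-axis measurement directions.
Fits are flagged when the achieved rank falls short of the coefficient
count. The expansion origin defaults to the centroid of the measurement
positions, which places the zero crossings of the gradient components
inside the mapped volume. Fields are stored per unit current (T/A), so
one model serves both the ~10 nT mapping regime and the sub-nT OPM
regime; real hardware may scale slightly nonlinearly between those
regimes, which is outside this model. Fit quality is reported as NRMSE —
RMS residual over RMS of the data.

## Driving the coils: harmonic synthesis

With per-coil coefficients collected into $B = [\beta_1 \ldots \beta_N]$,
the currents approximating a target composition $\tilde\beta$ are the
minimum-norm least-squares solution $\mathbf i = B^{+}\tilde\beta$. The
package warns when a requested component is achieved at less than half
its requested value (threshold 0.5, configurable — a heuristic; the
ratio is only evaluated for components carrying at least $10^{-3}$ of
the target's largest entry, since the ratio is numerically meaningless
for negligible entries). `synthesis_diagnostics()` reports the condition
number and rank of $B$, optionally restricted to the degree-$\le 2$
rows: a three-axis Helmholtz-like arrangement, for instance, spans only
two independent diagonal gradients and no transverse gradient, which
makes the linear position solve rank-deficient — the classic reason to
add a transverse-gradient coil.

## The staged calibration

1. **Linear gain/orientation.** For excitations whose fields are
   (approximately) uniform, $g\mathbf n = H^{+} \mathbf b_H$, where the
   rows of $H$ are the uniform parts of the fitted excitation models —
   *not* the requested targets, so imperfect synthesis is accounted for.
   Rank $< 3$ (collinear fields) is a hard error.
2. **Linear position.** Expanding each gradient excitation to first
   order, $b_i = g\mathbf n\cdot(\mathbf u_i + G_i(\mathbf r -
   \mathbf o))$ with uniform part $\mathbf u_i$ and gradient tensor
   $G_i$ at the origin $\mathbf o$; stacking rows
   $(g\mathbf n)^\top G_i$ gives
   $\mathbf r = G^{+}(\mathbf b_G - H_G\, g\mathbf n)$, relative to the
   expansion origin. With exactly degree-$\le 2$ fields and no noise,
   these two solves are already exact (verified to numerical precision).
3. **Fine-tune (optional).** Nelder–Mead on the SSE against the *full*
   VSH models of the same superposed excitations, all of them jointly.
4. **Final refinement.** Nelder–Mead on the SSE against the responses to
   every individual coil and its full model.

The refinement parametrization is the unconstrained 6-vector
$(g\mathbf n, \mathbf r)$ — gain and orientation are extracted afterwards
as norm and direction, avoiding an explicit unit-norm constraint. The
joint dual-axis variant for OPMs measuring two tangential components at
one physical location optimizes the 9-vector
$(\mathbf r, g_x\mathbf n_x, g_y\mathbf n_y)$, so the shared position is
exact by construction. Simplex settings are fixed for reproducibility:
relative objective tolerance $10^{-10}$, at most 5000 iterations per
start, up to two restarts from the incumbent (restarting a converged
simplex is standard practice against premature collapse), and parameter
scaling of 5 mm in position and 5 % in gain, which sets the initial
simplex size. The refiner never returns parameters worse than its
starting point, and warns if the solution leaves the coil models'
validity sphere.

## Dipole localization

Phantom coils are modelled as point magnetic dipoles,
$\mathbf B = \frac{\mu_0}{4\pi}\frac{3(\mathbf m\cdot\hat r)\hat r -
\mathbf m}{r^3}$. Channel amplitudes are linear in the moment, so the fit
is separable: a uniform grid (5 mm spacing in a 12 × 12 × 6 cm box under
the array by default) solves the moment by least squares at every node
and scores the residual (ties broken by first index), then Nelder–Mead
refines the position from the best node with the moment re-solved at
every evaluation. This keeps the nonlinear search three-dimensional. A
1 mm singularity guard rejects positions touching a sensor. Channels
whose time series correlate with the excitation reference below 0.9 —
after allowing integer-sample latencies within one period — are excluded
before fitting; in hardware such phase-shifted channels arise from
cross-axis projection errors, which this package does not model, but the
filter also removes noise-dominated (very low amplitude) channels in the
synthetic runs. At least six channels must survive to determine the six
dipole parameters.

## The synthetic ground truth

The simulator provides everything the hardware study would: coils,
mapping, sensors, noise and a phantom. Its defaults are the study
conditions and are not tuned per run.

* **Shield coils.** The true dimensions of the emulated system are not
  published, so the geometry is a plausible person-sized layout chosen
  once: 16 rectangular coils (0.45 × 0.5 m) in two rings of eight on a
  0.45 m-radius cylindrical form, plus two 0.40 m-radius circular end
  coils at $z = \pm 0.65$ m; one rectangular coil is marked broken,
  leaving 17 usable. Fields come from the exact finite-segment
  Biot–Savart formula (circles as 64-gons with area-matched radius).
* **Mapping.** A 6 × 6 × 3 grid of 108 triaxial positions (324 scalar
  values) spanning ±0.10 m transversely and −0.05…0.11 m vertically,
  covering the helmet region; mapping is noiseless (the idealization of
  a well-calibrated reference magnetometer). The fitted models reach
  worst-case NRMSE ≈ 0.3 % at $l_\max = 5$ — comfortably within the
  2 % regime expected of a far coil set.
* **Fluxgate validation.** Six triad placements with seed-jittered
  positions and orientations: 18 single-axis channels, 2 cm spacing
  along the probe axis, gain 0.1 V/µT with ±0.1 % scatter. Excitations
  are scaled so the largest field over the mapping region is 12.5 nT.
* **Noise and SNR.** Channels record
  $v(t) = g\,\mathbf B(t)\cdot\mathbf n + \varepsilon(t)$ at 1 kHz with
  a 20 Hz sinusoidal carrier, in 1 s blocks; lock-in demodulation over
  whole periods returns the signed in-phase amplitude. White noise of
  field-referred density $\rho$ gives an amplitude error of standard
  deviation $\rho\sqrt{f_s/N} = \rho/\sqrt{T}$, so the density is set
  from the target amplitude SNR at the maximum field —
  SNR ≈ 1900 at 12.5 nT gives $\rho \approx 6.6$ pT/√Hz, close to a
  real fluxgate noise floor. SNR, not the bandwidth accounting, is
  treated as the controlled quantity. The OPM mode uses 0.5 nT and
  SNR ≈ 10⁴ (sub-nT to stay within an OPM's ±1 nT linear range).
* **OPM array and phantom.** Six 4-channel sensors on a 0.09 m
  helmet-like cap (2 × 2 channel grids, 1.8 cm pitch), two tangential
  orientations per channel perturbed by ~2° so they are not exactly
  orthogonal, gains 1 V/nT ± 5 %. Nine dipoles of 140 nAm² sit 3–6 cm
  from the nearest channels; their field-referred amplitudes span tens
  to hundreds of pT across the array, as expected at these standoffs.
  Dipole amplitudes are forward-simulated through the **true** sensor
  parameters and fitted with the **calibrated** ones, so dipole position
  errors measure how calibration errors propagate to source
  localization.

All randomness flows from a single integer seed; identical seeds give
byte-identical scenarios and series.

### What the simulator does not emulate

Shield-wall polarization and image currents (the synthetic Biot–Savart
fields simply *are* the truth — in hardware this is precisely why one
maps rather than computes the fields), reference-magnetometer errors and
drift between mapping and calibration sessions, coil-driver DAC
quantization (a uniform-step quantizer is available but off by default),
OPM cross-axis projection error and gain nonlinearity across field
regimes. Passing the synthetic suite therefore demonstrates the
estimators' correctness and noise behaviour under ideal physics; it
bounds, but does not measure, performance on hardware, where these
systematic effects dominate the error budget.

## Validation problem sizes and observed behaviour

The packaged validation runs the fluxgate study over 18 channels × 10
noise seeds and the phantom study over 9 dipoles × 5 seeds — enough to
stabilize the RMS statistics while keeping a full run in the minutes
range on one CPU. The test suite additionally verifies, among others:
Maxwell constraints of every basis field by finite differences; exactness
of the linear stage on noiseless degree-$\le 2$ fields; the current
synthesis round trip inside the column space of $B$; monotonicity of the
refinement; inverse-crime dipole recovery to 0.1 mm; closed-form recovery
of rigid motions by the Umeyama alignment; and that calibration errors
scale approximately as 1/SNR across SNR ∈ [10², 10⁴]. The stage-by-stage
error histograms shrink from the linear initialization to the final fit,
and the final synthetic errors sit well below the RMS accuracy a hardware
system achieves at the same SNR, as they should once systematic hardware
errors are absent.

## Known limitations

* The VSH expansion is only valid inside the largest source-free sphere
  around the origin; evaluation outside warns rather than fails, and
  refinements that wander outside the mapped region are flagged.
* The linear position solve needs gradient diversity; coil sets without
  a transverse gradient fail with a rank error by design.
* Nelder–Mead is local: with a reasonable linear initialization this is
  the intended regime, but a deliberately absurd starting point can
  converge to a secondary minimum. The multi-coil SSE landscape makes
  this rare in practice.
* The dipole grid must contain the true position; the default box is
  matched to the phantom geometry and is configurable.
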