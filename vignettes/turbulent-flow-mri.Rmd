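---
title: "Synthesizing and reconstructing multipoint 4D flow MRI of turbulent flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing and reconstructing multipoint 4D flow MRI of turbulent flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Phase-contrast (PC) MRI with a bipolar velocity-encoding gradient of
strength $k_v = \pi/\mathrm{VENC}$ maps the voxel-mean velocity into the
signal phase and the *spread* of velocities inside the voxel into the
signal magnitude.  If the intra-voxel velocity distribution is Gaussian
with directional variance $\sigma^2$, the complex voxel signal is

$$ S(\mathbf{k}_v) \;=\; S_0 \,
   e^{-\sigma^2 |\mathbf{k}_v|^2 / 2}\, e^{-j\,\mathbf{k}_v\cdot\bar{\mathbf u}} . $$

In turbulent post-stenotic flow the directional variances along six
non-collinear encoding directions determine the Reynolds stress tensor
$R = \rho\,\mathrm{Cov}(\mathbf u)$, hence the turbulent kinetic energy
density $\mathrm{TKE} = \tfrac12 \mathrm{Tr}(R)$ (J/m^3^).  How faithfully a
4D flow exam recovers TKE depends on the interplay of spatial resolution,
temporal averaging and SNR — and that interplay is what this package
simulates end to end: ground truth in, synthetic signals out,
reconstruction back, errors quantified.

## The forward model, stage by stage

**Ground truth.**  `make_phantom_flow()` builds an analytic stand-in for a
resolved CFD solution: an eccentric cosine-constricted tube (area follows a
cosine over two diameters around the throat; lateral offset peaks at
`eccentricity * diameter`), a mass-consistent axial jet (each slice is
normalized to the instantaneous flow rate, so flux is conserved exactly),
and an axisymmetric RST envelope downstream of the throat that vanishes at
the walls and is positive semidefinite by construction.  Real gridded CFD
exports are ingested with `load_gridded_fields()`.

**Temporal footprint.**  An acquisition integrates flow over a window
$\Delta t$ around each frame time.  `temporal_window_average()` treats all
frames inside the closed window (periodic over the cycle) as the
measurement ensemble: the output RST is the window mean of per-frame RSTs
*plus* $\rho$ times the covariance of the per-frame mean velocities — so
temporal mean-flow variation masquerades as turbulence.  $\Delta t = 0$
is instantaneous (noise-free) encoding.

**Resolution.**  Finite resolution is modeled in k-space as apodization
with a truncated 3-D Gaussian MTF of per-axis standard deviation
$\sigma_G = \sqrt{8\ln 2}\, L/\Delta_L$, cut where each 1-D Gaussian falls
to amplitude 0.5.  The filtered RST carries a partial-volume term

$$ R_\Delta = \mathcal F^{-1}(\mathcal F(R)\circ\omega)
   + \rho\,\mathcal F^{-1}(\mathcal F(\bar{\mathbf u}\bar{\mathbf u}^T)\circ\omega)
   - \rho\,\bar{\mathbf u}_\Delta \bar{\mathbf u}_\Delta^T , $$

the covariance of the mean velocity within the point-spread function:
unresolved shear layers and walls become apparent turbulence.

**Noise.**  A fixed hypothetical scan-time budget ties SNR to the
acquisition: $\mathrm{SNR} = \alpha V \sqrt{\Delta t}$ with
$\alpha = 1.68$ (so $V = 8\ \mathrm{mm}^3$, $\Delta t = 5$ ms gives
SNR = 30).  `add_noise()` injects i.i.d. complex Gaussian noise of
standard deviation $\sigma_\eta = |\bar S_{ROI}|/\mathrm{SNR}$, where
$|\bar S_{ROI}|$ is the mean noise-free reference magnitude over the full
fluid mask.

## Reconstruction

Each direction is acquired at three encoding strengths (multipoint
acquisition) because a single VENC is sensitive only to a narrow IVSD
band.  `multipoint_combine()` estimates the directional velocity and IVSD
per voxel as a maximum-a-posteriori fit under the signal model with known
$\sigma_\eta$: flat prior on the velocity over $\pm\max(\mathrm{VENC})$,
log-uniform prior on $\sigma$ over a configured range.  The published
multipoint unfolding algorithm this emulates is not reproduced here; the
package's implementation-defined stand-in enumerates the posterior's
discrete phase-wrap modes (seeded from the lowest-strength point,
sequentially unfolded to the higher strengths; `init = "grid"` adds a
dense search), then refines the best mode with damped, fully vectorized
Newton iterations on $(\nu, \sigma^2)$.  Directional estimates are then
assembled by pseudoinverse: $r^* = \rho\,(H^T H)^{-1} H^T
\sigma^2_{k_v}$ for the RST (rows of $H$ built from the unit encoding
directions) and $u^* = (K^T K)^{-1} K^T \breve\nu$ for velocity.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `severity`, `eccentricity` | 0.75, 0.05 | – | the studied eccentric stenosis |
| `mean_Re`, `peak_Re` | 1000, 4000 | – | physiological aortic inflow |
| `rho`, `mu` | 1060, 3.5e-3 | kg/m^3^, Pa s | blood, Newtonian |
| source spacing `L` | 0.65 | mm | projection grid of the CFD fields |
| `alpha` | 1.68 | mm^-3^ ms^-1/2^ | calibrates SNR = 30 at 8 mm^3^, 5 ms |
| VENC ladder | 5, 1.5, 0.45 | m/s | **not a published value**; spans the phantom's velocity and IVSD range |
| `sigma_range` | 1e-4 – 10 | m/s | IVSD prior support; floor small enough to contribute < 1e-7 relative error |
| envelope threshold | 0.05 | – | ROI~1~ = ground-truth TKE ≥ 5 % of its spatiotemporal peak, closed morphologically |

Phantom free parameters with no stated value anywhere (tube diameter
25 mm, jet recovery length 8 diameters, turbulence envelope peaking 4
diameters downstream, radial/axial anisotropy 0.5, default peak TKE
100 J/m^3^, raised-cosine systolic waveform with mean 1 and peak 4) were
chosen once as physiologically plausible for aortic stenosis and are not
tuned against any published percentage: the published error figures depend
on large-eddy CFD solutions that are out of scope here, and the phantom
makes no claim of reproducing them.

## Numerical choices

* **MTF frequency normalization.**  The $\sigma_G$ formula leaves the
  k-axis units implicit.  The package measures frequency in cycles per
  source sample (Nyquist = 0.5), which makes $\Delta_L = L$ near-identity
  — the property the forward–inverse round-trip test relies on.  Under
  this convention the 0.5-amplitude cut falls beyond Nyquist for
  $\Delta_L < 5.5\,L$, so truncation is inert in the studied range.
* **Partial-volume sign.**  The truncated-Gaussian PSF necessarily rings,
  so the partial-volume term is *not* pointwise nonnegative at ideal
  velocity steps.  Its volume integral is nonnegative (DC weight 1 and
  weights ≤ 1 give $\sum|u_\Delta|^2 \le \sum|u|^2$ by Parseval), and its
  trace is positive at shear layers; tests assert exactly that.
* **Clamping.**  Negative IVSD variances (noise, or ringing of the
  partial-volume term) are clamped at the prior floor and counted —
  never silently absolute-valued — because the clamp count is itself a
  diagnostic of the noise floor.  No PSD projection of the reconstructed
  RST by default: negative eigenvalues are a genuine artifact signal
  (`psd_project = TRUE` is available).
* **Phases.**  $\breve\nu = \arg S(\mathbf k_v)$ with the reference phase
  subtracted per voxel, mapped to $(-\pi, \pi]$; aliasing ties break
  toward the estimate from the smallest $|k_v|$.
* **Boundaries.**  Periodic FFTs with ≥ 8 source voxels of zero padding;
  background voxels carry zero velocity/RST before filtering (signal
  void), and the reference magnitude is 0 outside the fluid.
* **Decimation.**  The filtered field is sampled at target-voxel centers
  by trilinear interpolation — the MTF already encodes the acquisition
  blur, so no extra box averaging.
* **Degenerate inputs.**  Zero-reference voxels are flagged and excluded;
  an all-zero velocity field gives $S_0 \equiv 0.5$; single-strength
  schemes fall back to the phase of that point plus the magnitude-ratio
  IVSD.

## What the synthetic world does and does not establish

The phantom emulates the *statistical structure* of post-stenotic flow —
a confined jet, a turbulent envelope lagging the waveform, no-slip walls,
mass consistency — but not its physics: no Navier–Stokes solution, no
cycle-to-cycle variability, no wall motion, no displacement artifacts, no
coil model.  A green test therefore establishes that the synthesis and
reconstruction operators are mutually consistent and that the error
*mechanisms* (partial volume, temporal averaging, noise floor) behave
monotonically as resolution and SNR degrade; it does not certify the
magnitude of errors for any real acquisition or reproduce CFD-dependent
published percentages.

Known limitations: isotropic target voxels only; ideal encoding (no
eddy-current or Maxwell terms); the Bayesian unfolding is an
implementation-defined stand-in for the published algorithm; the phantom
RST is axisymmetric with zero shear components, so off-diagonal RST
recovery is exercised only by the partial-volume term and synthetic unit
tests.
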