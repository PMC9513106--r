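# turbmri

Synthesis and reconstruction of multipoint (multi-VENC) phase-contrast
4D flow MRI of turbulent flow.

## Who this is for

4D flow MRI can map velocity and turbulent kinetic energy (TKE) in the
stenotic aorta, but the measured TKE is distorted by finite spatial
resolution (partial-volume averaging of shear layers), temporal averaging
over the cardiac cycle, and noise — and under a fixed scan-time budget
these cannot be improved independently, since `SNR = α·V·√Δt` couples
noise to voxel volume `V` and temporal footprint `Δt`.  `turbmri` gives
researchers developing or validating turbulence-sensitive flow MRI
methods a fully synthetic, ground-truth-paired testbed: generate a known
mean-velocity / Reynolds-stress field, simulate the acquisition at any
`(Δ_L, Δt)` operating point, reconstruct, and quantify the error.

## The model

Each voxel's complex PC-MRI signal under a Gaussian intra-voxel velocity
distribution is

    S(k_v) = S0 · exp(−k_vᵀ R_Δ k_v / (2ρ)) · exp(−j k_v·ū_Δ) + η,
    k_v = π/VENC · e

Band-limiting to MR resolution `Δ_L` is k-space apodization with a
truncated Gaussian MTF (σ_G = √(8 ln 2)·L/Δ_L); the filtered Reynolds
stress picks up a partial-volume term ρ·Cov(ū within the PSF).
Reconstruction inverts the chain: Bayesian multipoint unfolding of six
directional velocities ν̆ and variances σ², then pseudoinverse assembly

    r* = ρ (HᵀH)⁻¹Hᵀ σ²,   u* = (KᵀK)⁻¹Kᵀ ν̆,
    TKE = ½ Tr(R*),        KE = ρ|u*|²/2.

See the methods vignette (`vignettes/turbulent-flow-mri.Rmd`) for
assumptions, parameter defaults and numerical choices.

## Worked example

Steady flow through a 75 % eccentric stenosis, acquired at 1.5 mm and
2.5 mm isotropic with 5 ms temporal averaging under the scan-time-budget
noise law:

```r
library(turbmri)
grid <- grid3d(c(20, 20, 48), spacing = 0.75)
cfg <- run_config(
  stenosis = stenosis_spec(severity = 0.75, eccentricity = 0.05,
                           diameter = 12, throat_position = 1.0,
                           downstream_length = 1.9),
  inlet = inlet_spec(mean_Re = 1000),
  grid = grid,
  turb = turb_params(tke_peak = 100),
  conditions = data.frame(delta_L = c(1.5, 2.5), delta_t = 5),
  seed = 1L)
res <- run_pipeline(cfg)
print(res)
```

```
pipeline_result (config 200f7d0c, seed 1):
 condition delta_L delta_t      snr  roi pct_error_tke
         1     1.5       5 12.67851 ROI1     -6.451793
         1     1.5       5 12.67851 ROI2      7.590637
         2     2.5       5 58.69678 ROI1     15.091696
         2     2.5       5 58.69678 ROI2     30.504805
```

Reading this: `ROI1` is the envelope of the turbulent region, `ROI2` the
whole fluid lumen; `pct_error_tke` is the signed percent error of the
cycle-integrated total TKE against ground truth.  Coarsening from 1.5 to
2.5 mm inflates the whole-geometry error from ~8 % to ~31 % — partial
volume converts unresolved jet shear into apparent turbulence — while the
envelope ROI at high resolution slightly *under*-estimates (blur moves
TKE out of the envelope faster than noise adds it).  The `snr` column is
the budget law at each voxel volume: `snr_scan_budget(8, 5)` returns
`30.05275`, the calibration point of the noise model.

## Layout

- `R/` — phantom, sampling (MTF), mrsignal, recon, analysis, pipeline
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code)
- `inst/cli/synth.R` — command-line driver (`phantom`, `downsample`,
  `run`, `report`)
- `vignettes/turbulent-flow-mri.Rmd` — methods vignette
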