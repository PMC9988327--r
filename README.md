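# sidedmri

Reconstruction of full diffusion-weighted (DW) image volumes from
**slice-interleaved diffusion encoding (SIDE)** acquisitions.

Diffusion MRI normally spends one repetition time per diffusion wavevector,
so high angular resolution means long scans — a real problem for pediatric,
elderly and motion-prone subjects. SIDE, combined with simultaneous
multi-slice (SMS) excitation, interleaves slice groups carrying *different*
wavevectors inside each acquired volume: a *cycle* of `N_Q / N_SG` volumes
touches every wavevector once, successive cycles shift the assignment by
one slice group, and skipping cycles undersamples every wavevector's volume
at slice level. The total acceleration is `R_SMS * R_SIDE` (25-fold at
SMS 5 with every fifth cycle kept).

Recovering the unacquired slices is an ill-posed inverse problem. This
package implements the full method:

- **Scheme planning** — slice groupings, the cyclic SIDE schedule with its
  exactly-once coverage guarantee, and the matched-budget conventional
  (angular) undersampling comparator.
- **Signal model** — a restriction-spectrum dictionary
  `A = [R_1 Y_1 ... R_K Y_K | iso]` built from axially symmetric fiber
  responses `exp(-b((D_L - D_T)(q.v)^2 + D_T))` over a grid of
  diffusivities, times an even spherical-harmonic basis (order 8 by
  default) on a 321-direction hemisphere tessellation.
- **Reconstruction** — ADMM on

  ```
  min_E  1/2 Σ_{q,l} || H_l E w_ql - E^S_q(:,l) ||_F^2 + λ ||E||_TV
  s.t.   E^T = A V
  ```

  with a weighted isotropic 3-D total-variation semi-norm per DW volume
  (weights (0.9, 0.9, 1)), a dual-FISTA TV proximal operator, a cached
  Cholesky dictionary solve, a closed-form per-entry signal update, and the
  printed multiplier-change stopping rule. Defaults: `λ = 0.01`,
  `ρ1 = ρ2 = 0.5`.
- **Synthetic phantom** — a crossing/straight/isotropic fiber phantom with
  electrostatic-repulsion multi-shell gradients and seeded Gaussian or
  Rician noise, so everything runs with no external data.
- **Metrics** — NMSE and PSNR exactly as the evaluation protocol prints
  them (`||E - Ẽ||_F / N_Vox`; `10 log10(MAX / NMSE)`), 3-D SSIM matching
  the standard reference implementation, relative difference, fiber-bundle
  overlap, and GFA (std/rms of fODF amplitudes).
- **I/O and pipeline** — NIfTI-1 volumes, FSL bvals/bvecs, JSON scheme and
  provenance sidecars, a YAML-configured `run_pipeline()` and a CLI script
  (`inst/cli/sidedmri`) with `phantom / plan / forward / recon / eval /
  run` subcommands.

## Worked example

Simulate the default phantom, plan a SIDE scheme at `R_SIDE = 2`, acquire
with SNR-30 noise, reconstruct, and compare against the ground truth and
the zero-filled baseline:

```r
library(sidedmri)

spec <- default_phantom()                 # 16 x 16 x 12, shells b = 500/1000/2000
sim  <- synthesize(spec)                  # analytic truth + noisy copy

scheme <- plan_side(make_grouping(12, 3), n_q = 40, r_side = 2)
scheme
#> <side_scheme> N_Q = 40, N_SG = 4, 10 volumes/cycle, R_SIDE = 2
#>   (2/4 cycles acquired), total acceleration 6

obs  <- acquire(sim$truth, scheme, noise_sigma = spec$noise_sigma, seed = 103)
dict <- build_dictionary(sim$gradients, spectrum_grid(), sh_order = 8)
rec  <- reconstruct(obs, dict)            # ~100 ADMM iterations

metric_report(rec$E, sim$truth, gradients = sim$gradients)
#> <metric_report> NMSE 0.0027648 | PSNR 23.994 dB | SSIM 0.85987
#>   per shell:
#>     b  n        nmse     psnr
#>   500  8 0.001290419 27.30298
#>  1000 12 0.001660329 25.15054
#>  2000 20 0.001795051 23.02124

nmse(adjoint(obs), sim$truth)             # zero-filled baseline
#> [1] 0.02568786
```

The reconstruction fills the unacquired half of every DW volume to within a
few percent of truth (NMSE here is the printed-formula Frobenius norm over
the voxel count), an order of magnitude below the zero-filled baseline; at
the same acquired-volume budget, conventional angular undersampling
reconstructs to NMSE ≈ 0.026 — close to the zero-filled level, because
dropped wavevectors can only be interpolated angularly.

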