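---
title: "Slice-interleaved diffusion encoding: model, solver and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-interleaved diffusion encoding: model, solver and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The acquisition model

Conventional diffusion MRI acquires one full volume per diffusion
wavevector: with $N_Q$ wavevectors and a repetition time of a few seconds,
scan time grows linearly in the angular resolution. Slice-interleaved
diffusion encoding (SIDE) breaks the one-volume-one-encoding coupling.
With simultaneous multi-slice (SMS) excitation at factor $R_\mathrm{SMS}$,
the $N_z$ slices split into $N_\mathrm{SG} = N_z / R_\mathrm{SMS}$ slice
groups, each group holding one slice from each of the $R_\mathrm{SMS}$
bands of the volume (`make_grouping()`). A SIDE volume assigns a
*different* wavevector to every slice group, so $N_Q / N_\mathrm{SG}$
volumes — one *cycle* — touch every wavevector once. Successive cycles
shift the wavevector-to-group assignment by one group
(`plan_side()` uses the rule $q(c, m, g) = m N_\mathrm{SG} + ((g + c)
\bmod N_\mathrm{SG})$), so $N_\mathrm{SG}$ cycles cover every
(wavevector, slice group) pair exactly once. Skipping all but every
$R_\mathrm{SIDE}$-th cycle undersamples each wavevector's volume at slice
level by exactly $1/R_\mathrm{SIDE}$; the combined acceleration is
$R_\mathrm{SMS} R_\mathrm{SIDE}$.

Any bijective cycle offset satisfies the coverage property; the package
fixes the $+1$ shift and an evenly spaced acquired-cycle subset starting at
cycle 0 for reproducibility and maximal temporal incoherence. The
comparator scheme (`plan_conventional()`) models the standard alternative —
dropping wavevectors while keeping full volumes — allocating retained
directions per shell by largest-remainder rounding (remainder ties to the
larger shell) and spreading them within a shell by greedy farthest-point
selection.

## The signal model

Per voxel, the attenuation $E(\mathbf q) = S(\mathbf q)/S_0$ is modeled as
a spherical convolution of an axially symmetric fiber response with a fiber
orientation distribution (fODF). The response of a coherent bundle with
longitudinal and transverse diffusivities $D_L \ge D_T$ is

$$R(\mathbf q; \mathbf v) = \exp\!\big(-b\,[(D_L - D_T)(\hat{\mathbf q}
\cdot \mathbf v)^2 + D_T]\big),$$

and the fODF is expanded in real, even-order spherical harmonics
(`sh_basis()`, orthonormal, $P = (L+1)(L+2)/2$ functions at order $L$,
default $L = 8$, so $P = 45$). Because one diffusivity scale rarely
describes all compartments, the dictionary stacks several response blocks —
a restriction spectrum — plus single columns for isotropic compartments:
$A = [R_1 Y_1 \cdots R_K Y_K \mid \text{iso}]$ (`build_dictionary()`).
The default spectrum grid uses $D_L \in \{1.5, 2.0, 2.5\}\times10^{-3}$
mm²/s with, for each, a 3-point log-spaced transverse ladder from
$D_L/1.1$ down to $0.1\times10^{-3}$, and isotropic atoms at
$\{0.5, 1.5, 3.0\}\times10^{-3}$ mm²/s. The stated diffusivity *ranges*
fix the endpoints; the ladder density is a resolution/conditioning
trade-off — a denser ladder adds near-collinear columns that the damped
solve must suppress. Columns are normalized to unit Euclidean norm before
solving (atoms at different b-decay scales otherwise condition poorly) and
coefficients are rescaled to raw-column units on output. Isotropic atoms
are separate single columns rather than degenerate anisotropic blocks: an
isotropic response carries no angular content, so a full SH block would be
rank-1 padding.

The fODF reconstruction points are the 321 hemisphere vertices of a
thrice-subdivided icosahedron (`hemisphere_tessellation()`), which samples
order-8 harmonics comfortably.

## The reconstruction problem and solver

Collecting voxels as rows of $E \in \mathbb R^{N_\mathrm{Vox} \times
N_Q}$, the acquired slices define a masked least-squares data term; the
reconstruction solves

$$\min_{E}\; \tfrac12\sum_{q,l} \lVert H_l E w_{ql} - E^S_q(:,l)
\rVert_F^2 + \lambda \lVert E \rVert_{TV} \quad \text{s.t.}\quad
E^\top = A V,$$

where the TV term is the weighted isotropic 3-D total variation applied
per wavevector volume and the constraint ties every voxel's signal to the
spectrum model. The TV semi-norm uses forward differences with Neumann
boundary handling (differences past the last voxel are zero, so constants
have TV 0); the per-axis weights default to $(\gamma_x, \gamma_y,
\gamma_z) = (0.9, 0.9, 1)$, slightly favoring smoothing along the slice
axis where SIDE removes data. The published form of the TV integrand is
typographically ambiguous about parenthesization; the package implements
the standard isotropic weighted TV — one square root over the sum of the
three squared weighted differences per voxel — which is the only reading
that makes the expression a norm of the weighted gradient.

The augmented Lagrangian splits into four subproblems per ADMM iteration,
in this order:

1. **Coefficients** $V$: damped normal equations against the normalized
   dictionary, one Cholesky factorization cached and reused across all
   voxels and iterations (`update_V()`). The damping (default $10^{-6}$)
   regularizes the underdetermined spectrum fit; it acts as a proximal
   perturbation of the subproblem and does not prevent the multiplier from
   driving $E^\top - AV$ to zero.
2. **TV splitting** $U_q = \mathrm{prox}_{(\lambda/\rho_1)
   TV}(E^{(q)} - \Psi_q)$ for every wavevector independently
   (`update_U()`).
3. **Signal** $E$: the data, splitting and constraint terms are separable
   per (voxel, wavevector) entry, giving the closed form
   $E = (M \odot Y_{obs} + \rho_1 (U + \Psi) + \rho_2 (AV - \Phi)^\top) /
   (M + \rho_1 + \rho_2)$ (`update_E()`).
4. **Multipliers**: $\Psi_q \mathrel{+}= U_q - E^{(q)}$,
   $\Phi \mathrel{+}= E^\top - AV$.

$E$ is initialized at the zero-filled adjoint of the observations and the
multipliers at zero. The stopping rule is the conjunction of squared
multiplier changes, $\lVert \Psi^{(t)} - \Psi^{(t-1)} \rVert^2 \le
\varepsilon_1$ and $\lVert \Phi^{(t)} - \Phi^{(t-1)} \rVert^2 \le
\varepsilon_2$, or `max_iter` (default 100). This is unusual for ADMM —
the same quantities are the primal residuals, which the history logs
explicitly — but it is the printed algorithm and is kept as such. The
default tolerances are $10^{-8}$ per matrix entry: a per-entry scaling
keeps the rule problem-size-independent, and $10^{-8}$ was chosen because
looser settings ($10^{-6}$/entry) demonstrably stop the solver on small
phantoms after a handful of iterations, well before the primal residuals
plateau, costing a factor 3–4 in reconstruction error at high
undersampling. Divergence (objective exceeding ten times its running
minimum) aborts with a diagnostic.

### The TV proximal operator

`tv_prox()` solves $\min_U \tfrac12\lVert U - x \rVert^2 + t\,TV(U)$ by
accelerated projected gradient ascent (FISTA momentum) on the dual: dual
fields are per-voxel 3-vectors projected onto the unit ball, the dual step
is $1/(4(\gamma_x^2 + \gamma_y^2 + \gamma_z^2))$ scaled by $1/t$, and
iteration stops on a $10^{-5}$ relative change of the primal iterate or
after `inner_iters` (50 standalone, 30 inside the ADMM — the outer
multipliers absorb residual inexactness). Either the monotone or the fast
dual variant satisfies the same fixed-point equations; the package uses
the fast one. The prox is validated against an independent long-run
subgradient-descent oracle in the test suite; the oracle exploits the
strong convexity of the prox objective with a geometrically decaying step.

## The synthetic phantom

`default_phantom()` builds a 16 × 16 × 12 grid with three region types: a
straight left-right bundle (volume fraction 0.8, $D_L = 1.7\times10^{-3}$,
$D_T = 0.4\times10^{-3}$ mm²/s, 0.2 free-water fraction at
$3.0\times10^{-3}$), a 60° in-plane crossing (two populations at 0.4
each), and an isotropic background at $1.5\times10^{-3}$ mm²/s. Shells are
$b = 500, 1000, 2000$ s/mm² with 8, 12 and 20 directions placed by seeded
electrostatic repulsion — a scaled-down version of a 160-direction
four-shell protocol, sized so the full undersampling study runs in minutes
on one CPU. Noise is additive Gaussian with $\sigma = 1/30$ of the nominal
peak attenuation ("SNR 30"; Rician optional). Fiber populations are delta
fODFs, so ground truth is analytic; dispersion can be emulated with
mixtures of nearby directions.

What the phantom does *not* emulate: anatomy, partial-volume gradients at
tissue boundaries, spatially varying $S_0$, susceptibility or motion
artifacts, and g-factor noise amplification from SMS unaliasing. Passing
the phantom study therefore demonstrates correctness of the operators and
solver and the *direction* of the SIDE-vs-conventional effect, not
clinical image quality.

`matched_dictionary()` deserves a note: with a tessellation equal to the
phantom's fiber directions, the SH block has full row rank, so the
phantom's noiseless signals lie exactly in the dictionary's column space.
That makes the noiseless, fully sampled, $\lambda = 0$ configuration an
exact-recovery test of the solver with machine-accuracy expectations —
separate from SH truncation, which is tested independently (an order-8
delta-fODF projection reproduces the direct response to well under 2%).

## Numerical and degenerate-input choices

- b-values below 10 s/mm² are b0; b0 volumes normalize the attenuations
  and are excluded from $E$, since the model describes attenuation.
- Voxels with $S_0 \le 0$ are masked into a validity mask, not fatal.
- bvec files are accepted in 3 × N and N × 3 layouts, disambiguated by
  shape; the ambiguous 3 × 3 case is read as 3 × N with a warning.
- Attenuations above 1.5 warn (noise can exceed 1) but do not reject.
- Observations are stored dense (zero-filled) with an $N_z \times N_Q$
  slice-level logical mask; the mask enforces the slice-level sampling
  structure by construction, and at phantom scale a dense container is
  simpler and cheaper than a ragged per-slice-group layout.
- All solver steps are deterministic; the only randomness anywhere is the
  seeded phantom geometry and noise, so fixed seeds give bit-identical
  pipelines.

## Metric conventions

The package implements the NMSE and PSNR formulas *as printed* in the
evaluation protocol it follows: NMSE is $\lVert E - \tilde E \rVert_F /
N_\mathrm{Vox}$ — the norm (not its square) over the voxel count — and
PSNR is $10\log_{10}(\mathrm{MAX}/\mathrm{NMSE})$ with MAX the ground-truth
maximum. Both differ from the textbook definitions; the conventional
variants are available as `nmse_relative()` and `psnr_standard()`.
SSIM uses the standard constants ($K_1 = 0.01$, $K_2 = 0.03$, Gaussian
window $\sigma = 1.5$, 11³ support) computed in 3-D per wavevector volume
and averaged; it matches the widely used reference implementation to
numerical precision. GFA is std/rms (population std) of fODF amplitudes
over the tessellation, computed from the aggregate anisotropic
compartments. Fiber-bundle overlap is implemented as a generic
probability-map overlap $1 - \sum_i \lvert p_i - p^{GT}_i \rvert / \sum_i
p^{GT}_i$; tractography itself is out of scope.

## Study sizes and known limitations

The packaged undersampling study uses the default phantom (3072 voxels, 40
wavevectors), the full spectrum dictionary (408 columns) and the default
solver settings; a single reconstruction converges in up to 100 iterations
in under two minutes, and the whole study (SIDE at $R_\mathrm{SIDE} \in
\{1, 2, 4\}$ plus matched-budget conventional comparators) in a few
minutes. On this phantom, SIDE reconstruction at factor 2 reaches per-entry
relative errors of a few percent in well-attenuated entries and beats
conventional angular undersampling by an order of magnitude in NMSE at the
same volume budget — the same direction of effect reported for in-vivo
data, though magnitudes on a 16³-scale phantom are not comparable to a
128 × 128 × 100 brain.

Limitations: the solver holds the full $E$, $U$, $\Psi$ matrices in
memory ($O(N_\mathrm{Vox} N_Q)$ each), appropriate for phantom-scale and
single-slab problems but not whole-brain 1.5 mm data; $\rho_1, \rho_2$
are fixed (no adaptive penalty scheduling); the dictionary solve is dense;
and noise is treated as i.i.d. Gaussian on attenuations rather than
whitened per slice group.
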