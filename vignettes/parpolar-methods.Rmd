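---
title: "Model and methods behind parpolar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind parpolar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

parpolar simulates symmetry breaking of the *C. elegans* zygote cortex: how
the membrane becomes partitioned into mutually exclusive anterior (aPAR) and
posterior (pPAR) protein domains, with or without the centrosomal cue that
normally selects the posterior pole. This vignette documents the model, the
parameterization, the numerical scheme, and the design decisions a
maintainer would want to know about — including which features of real data
the synthetic fixtures do and do not emulate.

## The dynamical system

Membrane concentrations $A(x,t)$ (anterior species, per µm²) and $P(x,t)$
(posterior species) evolve on a 1D periodic domain — the cortex
circumference — under diffusion, advection by the cortical flow $v(x,t)$,
exchange with well-mixed cytoplasmic pools, and mutual antagonism:

$$\partial_t A = D_A \partial_x^2 A - \partial_x(vA)
  + k_{\mathrm{on},A} A_{\mathrm{cyto}} - k_{\mathrm{off},A} A - k_{AP} P A$$

$$\partial_t P = D_P \partial_x^2 P - \partial_x(vP)
  + k_{\mathrm{on},P}(x) P_{\mathrm{cyto}} - k_{\mathrm{off},P} P - k_{PA} A^2 P$$

Two couplings close the loop:

1. **Active-gel force balance.** The cortical flow obeys
   $\gamma v - \eta\,\partial_x^2 v = \partial_x(\Pi_{\mathrm{active}} +
   \Pi_{\mathrm{passive}})$ with
   $\Pi_{\mathrm{active}} = \Pi_0 - \beta P$: membrane-bound posterior
   protein lowers cortical contractility (via its antagonism with the
   anterior complex, which stabilizes myosin), so flows run *away from*
   P-rich, low-tension regions — the flow topology observed by particle
   image velocimetry, with anterior-directed flows in the wild type and
   center-directed flows from both poles in bipolar embryos. The passive
   (osmotic) stress is spatially constant and drops out of the gradient.
   The printed form of this equation admits either sign of the coupling;
   we fixed it by requiring the observed flow direction. The opposite sign
   (flows converging onto contractility minima) was implemented and tested:
   it compresses the posterior species into narrow spikes several-fold
   above its saturation concentration, unlike any observed distribution.

2. **Curvature-dependent attachment.** The posterior attachment rate is
   enhanced by excess membrane curvature over the central cortex,
   $k_{\mathrm{on},P}(x) = k_{\mathrm{on},P} + \alpha\,
   \max(\kappa(x)-\kappa_{\mathrm{ref}}, 0)$, without committing to a
   molecular mechanism. The clamp at zero encodes enhancement only — flat
   or concave regions keep the base rate.

Cytoplasmic pools are well mixed and slaved to mass conservation through
the surface-to-volume factor $\psi$:
$A_{\mathrm{cyto}} = \rho_A - \psi \langle A \rangle$ (same for P). Total
amounts are therefore conserved *by construction*, to machine precision;
the test suite asserts relative drift below $10^{-6}$.

## Parameters and their provenance

The exchange, diffusion and antagonism constants are the established
reaction–diffusion parameterization of the PAR system (µm, s, µm⁻²
membrane and µm⁻³ cytoplasmic concentrations):

| parameter | value | meaning |
|---|---|---|
| $D_A, D_P$ | 0.28, 0.15 µm²/s | membrane diffusivities |
| $k_{\mathrm{on},A}, k_{\mathrm{on},P}$ | 8.58·10⁻³, 4.74·10⁻² µm/s | base attachment |
| $k_{\mathrm{off},A}, k_{\mathrm{off},P}$ | 5.4·10⁻³, 7.3·10⁻³ s⁻¹ | detachment |
| $k_{AP}, k_{PA}$ | 0.19 µm²/s, 2.0 µm⁴/s | mutual antagonism |
| $\rho_A, \rho_P$ | 1.56, 1.0 µm⁻³ | conserved totals |
| $\psi$ | 0.174 µm⁻¹ | surface-to-volume factor |

With these values the uniform anterior-dominant state (A ≈ 1.51 µm⁻²,
P ≈ 0.01) and the saturated posterior state (P₀ ≈ 3.05 µm⁻²) are both
stable: the system is bistable, and a posterior domain is a pinned front
whose width is set by depletion of the cytoplasmic posterior pool
(wave-pinning). This bistability is essential — a softened antagonism
($k_{PA} \lesssim 0.1$) lets trace levels of membrane P destabilize the
anterior state everywhere.

The mechanical constants are the package's own calibration, expressed in a
stress unit where the membrane friction is $\gamma = 1$: cortex viscosity
$\eta = 196$ (hydrodynamic length $\sqrt{\eta/\gamma} = 14$ µm), baseline
active stress $\Pi_0 = 5$ (sets the trigger-driven flow amplitude to the
order of 1 µm/min), and the trigger patch described below.

**Nondimensional dials.** The two phase-diagram coordinates are the
dimensionless attachment gain $\alpha/l$ and contractility feedback
$\beta\tau/(\rho P_0)$, mapped onto dimensional parameters through the
reference scales $l = 10$ µm, $\tau = 1/k_{\mathrm{off},P} \approx 137$ s,
$P_0 = 3.0487$ µm⁻² and $\rho = 0.0225$:
$\alpha = (\alpha/l)\, l\, k_{\mathrm{on},P}$ and
$\beta = [\beta\tau/(\rho P_0)]\, \rho P_0 / \tau$. These scales are free
constants of the model family; they were fixed *once* by requiring that the
single printed reference point of the parameter plane, $(\alpha/l,
\beta\tau/\rho P_0) = (1.2, 100)$, reproduces all four reported phenotypes
simultaneously (single posterior domain with a posterior trigger; two polar
domains without a trigger; one corner domain in the triangular geometry
with and without a trigger) and were not revisited afterwards. At that
point $\beta = 0.05$, giving peak flows of 0.4–1 µm/min: in this model the
advective coupling shapes the speed and robustness of polarization, while
domain confinement itself comes from pool depletion. Much stronger coupling
($\beta \gtrsim 0.2$) lets advection push the posterior front past its
pinning point and P takes over the whole membrane — the model's version of
"very strong reduction of cortical active stress" breaking polarity.

## Scenarios

A scenario is a geometry plus a trigger. The trigger models the local cue
as a multiplicative reduction of the baseline active stress over a Gaussian
patch (width 8 µm) that decays exponentially with time constant 300 s —
the few-minutes duration of the flow-inducing cue:

- **wt** — full-depth patch at the posterior pole of the ellipse.
- **no-trigger** — no patch; symmetry is broken deterministically by the
  curvature-dependent attachment at the two poles. (This is the
  AIR-1-depleted condition: no local cue, intact machinery.)
- **weak-anterior** — quarter-depth patch at the anterior pole (the
  meiotic-arrest condition that recruits posterior protein anteriorly).
- **lateral** — full-depth patch at 0.35 of the circumference. The exact
  lateral midpoint (0.25) is equidistant from both poles — a measure-zero
  symmetric configuration where no relaxation direction is defined — so the
  default represents a generic lateral cue site.
- **triangle-wt / triangle-no-trigger** — same triggers on the
  embryo-in-triangular-chamber geometry.

**Geometries.** The ellipse is 50 × 30 µm (zygote proportions); its polar
curvature $a/b^2 \approx 0.111$ µm⁻¹ exceeds the lateral baseline
$b/a^2 = 0.024$ µm⁻¹ over two broad polar arcs. For the triangular
microchamber, the package distinguishes the *chamber* (a rounded
equilateral triangle, `triangle_curvature()`: flat sides, three arcs of
curvature $1/r$) from the *embryo squeezed into it*
(`embryo_triangle_curvature()`), which is what the triangle scenarios
simulate: a convex cortex contour of perimeter 110 µm whose curvature
peaks over three narrow (3 µm) corner-contact arcs — slightly unequal
(excess 0.140/0.130/0.119 µm⁻¹), as a real embryo presses hardest into one
corner, which is where domains were observed to form — and bulges gently
along the walls (baseline fixed by the 2π turning of a closed convex
curve). The distinction matters: a cortex that literally followed the
chamber wall would either present corner arcs so sharp that all three
nucleate domains at the reference point, or, with gentle rounding, would
have high-curvature arcs covering most of the perimeter so that no
confined domain can form. The narrow-contact profile reproduces the
observed behavior: one domain in the most-curved corner at moderate
parameters, an abrupt transition to two and then three domains at high
attachment gain.

## Numerical scheme

Each step of the compiled (Rcpp) integrator performs, in order: the
force-balance solve (cyclic tridiagonal system, second-order centred
differences); first-order upwind advection in conservative flux form keyed
to the sign of the face velocity; exchange and antagonism kinetics with
explicit gains and *implicit linear sinks*, which preserves positivity
unconditionally; implicit diffusion (cyclic tridiagonal). Cytoplasmic
pools are recomputed algebraically from conservation after every update.
The standalone `solve_force_balance()` uses a spectral (FFT) solve —
exact for the constant-coefficient operator — and is cross-checked in the
tests against both the closed-form single-Fourier-mode solution and dense
matrix solves; the core's finite-difference solver has its own dense
oracle.

Time steps respect 0.2× the upwind CFL limit, capped at `dt_max = 0.25` s
(the stiffest reaction, $k_{PA}A^2 \approx 4.6$ s⁻¹, is handled by the
implicit sink update, which is unconditionally stable and exact at fixed
points). Convergence is declared when $\max_x |\partial_t P| \cdot \tau /
P_0 < 10^{-6}$, never earlier than 4 trigger decay times (or 1500 s without
a trigger) so that slowly growing instabilities are not mistaken for
steadiness; non-convergence is flagged, and such runs are classified on the
time average of the last 10% of their kymograph. Mirror-symmetric scenarios
stay mirror-symmetric to ~10⁻¹³ over full runs (the scheme commutes with
reflection up to rounding), and doubling the grid from 128 to 256 points
moves domain boundaries by well under 1% of the circumference.

**Problem sizes.** Scenario runs use 256 grid points with a 20 000 s
horizon (seconds of wall time each); phase diagrams use 96 points, a
16 000 s horizon and a 10⁻⁵ tolerance over 10×10 parameter grids, chosen
so a full five-scenario sweep completes in minutes while leaving the
classification of every tested cell unchanged relative to finer settings.

## Classification and the phase diagrams

`count_domains()` counts maximal contiguous runs above
$0.5 \cdot \max_x P$ (periodic wrap respected), *provided*
$\max_x P > 0.35\, P_0$. The absolute floor distinguishes broken-through
domains (peaks ≥ 2.5 µm⁻²) from the sub-threshold curvature-boosted
background (≤ 0.4 µm⁻²); a relative threshold alone would call domains on
such profiles.

`classify_point()` labels a parameter-plane cell by the domain count of
the deterministic standard start (uniform membrane, plus the scenario's
trigger). For untriggered scenarios that develop at least one domain, it
additionally probes multistability from posterior-biased starts at each
high-curvature site, reporting `coexist-1/2` where a polar state persists
alongside the bipolar outcome — the polar/bipolar coexistence region.
Triggered scenarios are not probed (their initial condition is physically
determined), and sub-threshold cells are labeled 0 even though a
pre-seeded domain would persist there: surviving is not spontaneous
symmetry breaking. The sweep also records `n_uniform`, the uniform-start
count, which is what region-containment comparisons between scenarios use.

## Measurement operators

**Domain extent** (`domain_extent()`): 23-point *circular* moving average
(the trace is a closed circumference); noise floor = mean of the smoothed
trace's lower quartile, with a noise scale estimated from the lower-tail
quantile spread (5th to 25th percentile mapped to a normal sigma), so the
signal itself cannot inflate it; squaring of the smoothed trace; existence
threshold at the squared level $(\mathrm{floor} + 6\,\mathrm{scale})^2$
on the positive side; boundaries then localized at the half-height
crossing of the smoothed trace. The order of squaring versus thresholding,
and the exact floor statistic, are under-determined in the source
procedure; this combination is recorded as a package decision. It was
chosen because it is well defined and simultaneously satisfies all three
recovery requirements: exact width recovery on noiseless profiles
(half-height localization is unbiased under symmetric smoothing, where a
low threshold alone overestimates widths by up to the smoothing window),
extents within 5% of truth at SNR ≥ 5, and a false-domain rate well below
5% on pure-noise traces.

**PIV** (`piv_multipass()`): four cross-correlation passes with windows
64→32→16→8 px, half-window overlap and a 4 px final step; each pass
offsets the second frame's windows by the previous (rounded) estimate,
with periodic wrap (exact for the periodic synthetic benchmarks); 3-point
Gaussian subpixel fit per axis; Gaussian window taper (width 0.35 of the
window), which suppresses the subpixel bias caused by speckles truncated
at window edges (without it the error on a 0.3 px translation is ~0.11 px
RMS; with it, ~0.08); textureless windows flagged invalid and filled from
valid neighbors. `flow_kymograph()` averages the x-velocity along y per
frame pair, stacks rows into a kymograph in µm/min (refusing physical
units when pixel size or frame interval is missing), and summarizes a
movie by the maximum of the 3-frame temporally smoothed absolute profile.

## Synthetic data: what it does and does not emulate

`make_profile()` builds circumferential fluorescence traces as smooth
top-hats (half-cosine shoulders, 6% of the domain width) plus additive
Gaussian noise; `make_speckle_movie()` renders uniformly placed particles
as Gaussian spots advected by a prescribed field (uniform, sinusoidal, or
bipolar-inward) with periodic wrap, optionally with Poisson photon noise.
Seeds fix every output bit-exactly, and ground truth travels with the
fixture (including through text-file round trips).

These fixtures validate the *operators*, not the imaging: they do not
emulate background gradients, bleaching, out-of-focus light, embryo
outline curvature in the image plane, speckle appearance/disappearance
through cortical exchange, or out-of-plane motion. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
noise model, not performance on raw micrographs (whose preprocessing —
straightening, background subtraction, temporal alignment — is outside
this package's scope).

## Known limitations

- The analysis is 1D; azimuthal structure, 2D flow patterns and explicit
  centrosome mechanics are out of scope by design.
- The Appendix-level parameter set of the original physical description
  was not available to this implementation; the reference scales are a
  calibration anchored to the single printed coordinate pair, so
  quantitative positions of phase boundaries are package-specific, while
  the region topology (which regions exist, how they contain one another,
  how triggers shift them) is the reproducible content.
- Exact phase-boundary positions are classification-policy-dependent near
  threshold; `"nc"` cells (a few per 100 at sweep resolution) mark slow
  dynamics near boundaries rather than solver failure.
- The curvature-sensing mechanism is phenomenological (a linear gain on
  clamped excess curvature), as in the source description.

## Reproducing the headline numbers

```{r, eval = FALSE}
library(parpolar)
p <- set_dials(model_params(), alpha_over_l = 1.2, beta_scaled = 100)

sim <- run_to_steady_state("no-trigger", p)
count_domains(sim) # 2: one domain at each pole
autoplot(sim)

d <- phase_sweep("no-trigger", seq(0, 3, length.out = 10),
  10^seq(1, 3, length.out = 10), model_params(),
  grid_n = 96, t_max = 16000, tol = 1e-5
)
glance(d)
```

`scripts/acceptance.R` recomputes every headline quantity from scratch
(scenario domain counts, lateral relaxation, phase-region cell counts,
conservation/solver errors, and measurement-recovery metrics) and writes
them to a JSON report; see the README for how to run it.
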