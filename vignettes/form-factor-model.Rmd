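---
title: "The ffmc model: an empirical form-factor function and its Monte Carlo use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ffmc model: an empirical form-factor function and its Monte Carlo use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffmc)
```

## The quantity being modelled

The atomic form factor `f(q, Z)` is the Fourier transform of an atom's
electron charge density: it equals the electron count `Z` at zero momentum
transfer and decays monotonically with `q`. It enters the Rayleigh
(coherent) photon-scattering differential cross-section as

$$\frac{d\sigma}{d\Omega} \propto \frac{1 + \cos^2\theta}{2}\, f(q, Z)^2,
\qquad q = \frac{4\pi}{\lambda}\sin(\theta/2),$$

with the Thomson free-electron shape in front. Reference tabulations of
`f` are sparse in `q`, which forces transport codes into interpolation;
`ffmc` instead evaluates a closed-form function.

## The empirical function

The one-electron (hydrogen) form factor has the exact nonrelativistic
closed form

$$F_H(q) = \left[1 + \left(\frac{q a_0}{2}\right)^2\right]^{-2},$$

with `a0 = 0.52978` Å. The package generalizes it, per element, to

$$F(q, Z) = Z\,\left[\frac{a_1}{a_1 + b_1 x^2}\right]^{r}
\cdot \frac{a_2}{a_2 + b_2 x^2}
\cdot \frac{a_3}{a_3 + b_3 x^2},
\qquad x = \frac{a_0 q}{2},$$

seven free parameters per element: a hydrogen-like leading factor whose
shape exponent `r` is free, and two additional Lorentzian factors that act
as broad corrections. Design properties, all enforced by tests:

* **Normalization.** Every factor equals 1 at `q = 0`, so `F(0, Z) = Z`
  exactly for any positive parameters — the form-factor sum rule.
* **Hydrogen reduction.** With `r = 2`, `a1 = b1 = b2 = b3 = 1` and
  `a2 = a3 = 0`, the correction factors vanish identically for `q > 0`
  and `F` reduces to `F_H` — but at `q = 0` they become the indeterminate
  form 0/0. The stored hydrogen row therefore carries `a2 = a3 = 1E5`
  instead: the correction factors stay within
  `x²(50)/10⁵ ≈ 1.75 × 10⁻³` of unity over the whole calibrated range, and
  the pair of them leaks a maximum deviation of 0.35% at `q = 50`
  (recomputed by the acceptance script).
* **Monotonicity.** Each factor is strictly decreasing in `q` for positive
  parameters, so `F` is; this is checked diagnostically on dense grids but
  not enforced for arbitrary user parameters.
* **No branch on Z.** The 1E5 device is data in the parameter table, not a
  special case in code.

For user-supplied degenerate parameters with some `a_i = 0` the package
resolves the 0/0 form at `q = 0` by continuity from `q > 0` (the factor is
identically zero there, so the limit is 0).

### The parameter table

`inst/extdata/table1_parameters.csv` holds one row per element `Z = 1–30`:
the seven parameters plus the quoted deviation statistics of the original
calibration against the standard nonrelativistic reference tabulation.
The file stores verbatim decimal strings (including `5.8E-4`-style
scientific notation) and is parsed to double on load, so the packaged data
can be diffed character-by-character against its source. The quoted
maximum deviations obey the accuracy bands ≤3% (Z = 1–11), ≤4%
(Z = 12–22), ≤5% (Z = 23–30), and the quoted means are ≤2.25% throughout.

### A known tension in the hydrogen row

The quoted hydrogen-row statistics (max 0.49407, mean 0.30869, sd 0.16277
percent) describe the calibration against a *printed* reference table.
The analytic pair — empirical function with the hydrogen row versus the
closed form — can only show the 1E5-device leak, which grows monotonically
to 0.35% at `q = 50`. A monotonically growing deviation cannot produce a
mean/max ratio of 0.62 on any plausible grid, so the quoted statistics are
dominated by something else; their pattern (max just under 0.5%, mean
0.31%) is exactly what rounding a reference table to about three
significant figures produces. The package therefore reports the analytic
leak (0.35%) when asked to recompute this quantity on a dense grid, and
keeps the quoted 0.49407 as table data. Settling the difference requires a
reference tabulation with more digits, which is not shipped.

## Momentum-transfer conventions

Two conventions coexist in the literature: `q = (4π/λ) sin(θ/2)` and
`x = sin(θ/2)/λ`. The evaluator is convention-free (it consumes `q`
directly); the convention only matters when converting angles at a fixed
photon energy. The package defaults to the `4π` convention, under which a
sparse sampling table on `q = 0–16 Å⁻¹` covers the full angular range for
photon energies up to `hc·16/(4π) ≈ 15.8 keV` — consistent with the 2.5,
5, 7.5 and 10 keV demonstration energies used throughout. The
`inverse_lambda` switch on `scatter_kinematics()` exposes the alternative;
every kinematics-dependent CLI run logs the convention in force. The
conversion constant is `hc = 12.398419 keV·Å`.

## Refitting engine

`fit_parameters()` refits the seven parameters to any reference table by
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on
*relative* residuals `F_model/f_ref − 1`: `f` spans four orders of
magnitude over `q = 0–50`, the quality measure of the field is percent
deviation, and absolute residuals would let the `q ≈ 0` region dominate.
Box bounds are `r ∈ (0, 10]`, `a_i ∈ (0, 10⁶]`, `b_i ∈ (0, 10²]` — wide
enough to contain every packaged row including the 1E5 device. Multi-start
strategy: one start at the packaged row for the table's element (when it
exists), the rest log-uniform draws within the bounds from a fixed seed,
so fits are reproducible. The engine demands ≥20 points spanning at least
`[0, 10] Å⁻¹`; with fewer or narrower data the seven parameters are badly
underdetermined. Function-space recovery (deviation of the refit curve
from the data) is the contract; parameter identifiability is *not* —
distinct parameter vectors can represent near-identical curves, so tests
assert recovered curves (objective ≤ 1e−8, deviation ≤ 0.1%), never
recovered parameter values.

## Monte Carlo angle sampling

The sampler factorizes the coherent angular density into the `F²`
weighting and the Thomson shape:

1. Build the cumulative integral of `F(√u)²` over `u = q²` from 0 to
   `q_max² = q(θ=π)²`, normalized to 1 (`build_cumulative_F2()`; uniform
   `q²` grid, trapezoid rule, default 1024 points).
2. Draw `u ~ U(0,1)`, invert the cumulative by linear interpolation to get
   `q²`, and convert through the kinematics: `cosθ = 1 − 2 q²/k²` with
   `k = 4π/λ` (so `q_max = k` at `θ = π`).
3. Accept with probability `(1 + cos²θ)/2`, else redraw. The rejection
   function is bounded below by 1/2, so the overall acceptance rate lies
   in (1/2, 1] — recorded on every batch.

The two-stage factorization (inverse-CDF on `∫F² dq²`, then Thomson
rejection) is the standard scheme for form-factor sampling in transport
codes; the package adopts it as its reconstruction of the predecessor
sampler the sparse-table comparison emulates. Sampling is bit-reproducible:
every entry point takes an explicit seed, seeds a local Mersenne–Twister
stream, and restores the caller's RNG state afterwards.

**Analytic vs table mode.** In `analytic` mode the cumulative is built
from the empirical function on the dense uniform grid. In `table_lit`
mode `F` is linearly interpolated between the nodes of a sparse table
(LIT), *then* squared — interpolating `F`, not `F²`, as table-driven codes
do — and the cumulative is accumulated on the table's own `q²` nodes.
Sampling through that coarse piecewise-linear CDF is what distorts the
angular density; `noise_metric()` quantifies the distortion as the Pearson
reduced chi-square of a sampled histogram against the deterministic
density, and `compare_modes()` runs the paired experiment (default LIT
table: 85 nodes on `q = 0–16 Å⁻¹`, the sparse-grid scenario of a
production transport code) with a sign test for the direction
analytic ≤ LIT.

**Chi-square bookkeeping.** Expected counts come from per-bin Simpson
quadrature of `dcs(θ) sinθ` (50 uniform θ bins on `[0, π]` by default);
adjacent bins are merged until every expected count is ≥5, at least 10
usable bins are required, and the statistic is divided by (bins − 1). For
a correct sampler the reduced chi-square fluctuates around 1 with standard
deviation `√(2/dof) ≈ 0.2` at ~50 bins — a single run landing at 1.25 is
ordinary, which is why grid-level checks in the test suite pool the
statistic over all 16 element–energy combinations (pooled sd ≈ 0.05)
rather than asserting a ±1σ band per run.

## What the fixture generator emulates — and what it does not

`generate_fixture()` evaluates one of the two closed forms on a uniform
grid; the default (85 points on `[0, 16] Å⁻¹`) reproduces the sparse-table
scenario that motivates the analytic replacement. Because fixtures are
generated from the package's own closed forms, self-consistency tests
(deviation 0 against the generating parameters, exact write/read
round-trips) say nothing about agreement with *real* reference
tabulations, which differ by the quality of the underlying atomic model,
by rounding of printed digits, and — above a few tens of keV near
absorption edges — by anomalous-scattering corrections that are out of
scope here. The banded-accuracy audit against real tables therefore runs
on the *quoted* statistics shipped with the parameter table; recomputing
it requires user-supplied reference files via `read_ff_table()`.

## Numerical choices and problem sizes

* Trapezoid rule on a uniform `q²` grid for `∫F² dq²` (tolerance: <0.1%
  change on grid doubling, asserted); Simpson on θ for shape integrals and
  per-bin expected counts.
* `theta_of_q()` clamps its argument into `[−1, 1]` before `asin` to
  absorb floating-point overshoot at `θ = π`; round-trip accuracy 1e−12.
* Extrapolation beyond `q = 50 Å⁻¹` warns but evaluates; negative or
  non-finite `q` is an error.
* Test problem sizes: dense-grid deviation checks at 5001 points;
  sampler goodness-of-fit at 10⁶ photons per element–energy combination
  (16 combinations), LIT comparison at 10⁶ photons × 10 paired seeds;
  unit-level sampler checks at 10⁴–2×10⁵ photons. These sizes put the
  Monte Carlo standard error well below every asserted tolerance.

## Limitations

* Parameters exist only for `Z = 1–30`; beyond zinc the calibrated
  accuracy limit of the functional family is exceeded (refitting user
  tables for heavier elements is possible but uncharted).
* Nonrelativistic form factors only: no anomalous scattering factors, no
  relativistic or modified form factors, no S-matrix values.
* Angular shape only: no absolute cross-sections in barns, no photon
  transport (free paths, multiple scattering, geometry), no incoherent
  scattering.
* The quoted per-element deviation statistics are table data from the
  original calibration; only the hydrogen row can be recomputed without
  external reference files (see the tension noted above).
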