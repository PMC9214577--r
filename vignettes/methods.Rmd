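---
title: "Quantifying head tissue optical properties from multidistance CW-NIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying head tissue optical properties from multidistance CW-NIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Continuous-wave near-infrared spectroscopy measures steady-state diffuse
reflectance of red/near-infrared light at several source-detector separations
(SDS) on the scalp. The measured intensities depend on the absorption
coefficient $\mu_a(\lambda)$ and the transport scattering coefficient
$\mu_s'(\lambda) = \mu_s (1-g)$ of every tissue the photons traverse: scalp,
skull, cerebrospinal fluid (CSF), gray matter, and white matter. Quantifying
the subject's own $\mu_a$ and $\mu_s'$ matters because partial pathlengths —
and hence the conversion of intensity changes into hemoglobin concentration
changes, or the light dose delivered to cortex in photobiomodulation — vary
substantially between heads.

Diffusion-approximation inversions cannot represent the low-scattering CSF
layer ($\mu_s' \approx 1\text{--}3.7\ \mathrm{cm^{-1}}$), so this package
builds the forward model by voxel-based Monte Carlo (MC) photon transport and
makes the inverse problem tractable through three accelerations: white Monte
Carlo, a transport-scattering lookup table, and a trained neural-network
surrogate. `headfit` implements that pipeline end to end, with a synthetic
voxel head generator standing in for MRI segmentation.

## Spectral parameterization

Rather than fitting two optical properties per wavelength, each fitted tissue
is described by a handful of physical parameters:

* scattering follows the inverse power law
  $\mu_s'(\lambda) = A\,\lambda^{-K}$ with $\lambda$ in nm. Internally the
  amplitude is reparameterized as $\mu_s'(800\,\mathrm{nm})$ plus $K$, which
  keeps both parameters on bounded, comparable scales
  ($A = \mu_{s,800}' \cdot 800^{K}$ spans many orders of magnitude and is
  hostile to box-constrained optimization);
* absorption mixes chromophores:
  $\mu_a(\lambda) = 2.303\,[\varepsilon_{HbO}\,StO_2 +
  \varepsilon_{Hb}(1-StO_2)]\,tHB + \sum_i \mu_{a,i}(\lambda) C_i$
  with total hemoglobin $tHB$ (molar), oxygen saturation $StO_2$, and fixed
  volume fractions: scalp 75% water + 2% collagen (plus a fitted melanin
  fraction), gray matter 75% water. Skull absorption is hemoglobin only.
  CSF optical properties are fixed spectra; white matter is coupled to gray
  matter ($\mu_{a,WM} = \mu_{a,GM}/2$, $\mu_{s,WM}' = 3\mu_{s,GM}'$).

The free parameter vector has 13 entries (5 scalp, 4 skull, 4 gray matter).
Allowed per-compartment ranges for the derived $\mu_a$ and $\mu_s'$
(`op_ranges()`) both bound the lookup grid and act as the nonlinear
constraint of the fit.

### Chromophore tables

The packaged spectra (`inst/extdata/chromophores_synthetic.tsv`) are a
*synthetic emulation* of the standard published tabulations: anchor values at
reference wavelengths carrying the characteristic features — the
deoxy-hemoglobin 760 nm shoulder, an exact isosbestic point near 797 nm, the
water 970 nm band, a collagen bump near 910 nm, a $\lambda^{-3.48}$ melanin
power law — spline-interpolated to 1 nm on 650–1050 nm. They are adequate for
synthetic-data studies and unit contracts ($\varepsilon$ in
$\mathrm{cm^{-1} M^{-1}}$ against $tHB$ in M; $\mu_{a,i}$ of the pure
chromophore against volume fractions); for real measurements, substitute a
measured tabulation via `chromophore_library(path=)`. The fixed CSF
absorption follows the water shape rescaled into its allowed
0.015–0.1 $\mathrm{cm^{-1}}$ band; CSF scattering declines linearly from 2.8
to 2.0 $\mathrm{cm^{-1}}$ across the band. Default tissue parameters
(`tissue_params()`) were chosen once as physiologically typical values
(e.g. scalp $tHB = 60\ \mu M$, $StO_2 = 0.7$, melanin volume fraction 0.1%,
$\mu_{s,800}'$ of 15 / 16 / 9 $\mathrm{cm^{-1}}$ for scalp / skull / gray
matter) and produce optical properties comfortably inside the allowed ranges.

## Monte Carlo engine

`run_white_mc()` / `run_absorbing_mc()` transport photons through the label
volume with Henyey–Greenstein scattering ($g = 0.9$ for all tissues), exact
ray–voxel traversal (per-compartment pathlengths are exact per step), and
Fresnel reflection/refraction only where the refractive index changes: the
outer boundary (tissue 1.4 against fiber/pad medium 1.457) and sinus pockets
(1.0). Launch is a uniform disc (bundle radius 2.1 mm, NA 0.39) or a pencil
beam for oracle tests; specular reflection at launch follows the analytic
Fresnel coefficient.

White mode sets $\mu_a = 0$ everywhere and records each detected photon's
pathlength $PL(i,l)$ in every compartment; reflectance for any absorption
follows from the microscopic Beer–Lambert law
$$R = \frac{1}{N_{total}} \sum_i w_i\,
  e^{-\sum_l \mu_{a,l} PL(i,l)},$$
(`wmc_reflectance()`), so one scattering-only simulation serves the whole
absorption range. Absorbing mode carries the $e^{-\mu_a s}$ weight explicitly
and is the package's independent oracle: the two must agree within Monte
Carlo error, and the absorption-weighted mean partial pathlength equals
$-\partial \ln R / \partial \mu_{a,l}$ — both are asserted in the test suite.

Numerical choices worth knowing:

* **Detection.** Discrete mode tests literal fiber footprints (core radius
  0.2 mm) and acceptance cones ($\sin\theta \le \mathrm{NA}/n_{fiber}$;
  NA $\ge 1$ accepts everything, the lookup-table acceleration). Radial mode,
  valid for laterally invariant slabs, scores the exit displacement from the
  launch point into an annulus around each SDS with statistical weight
  $A_{det}/A_{annulus}$ — the classical $R(r)$ convolution device. It raises
  photon economy by two to three orders of magnitude and is what makes
  desk-scale lookup tables feasible; its smoothing bias (annulus half-widths
  of 1.5–2.5 mm against the local slope of $R(\rho)$) is identical between
  the lookup table and the validation targets generated with the same
  settings, so it largely cancels in the inverse problem.
* **Termination.** White-MC photons are capped at 150 cm cumulative path
  (configurable); beyond the cap the Beer–Lambert weight at the smallest
  absorptions of interest ($\mu_a \ge 0.05\ \mathrm{cm^{-1}}$ for the
  phantom compartments) is below $e^{-7.5}$. On top of the cap, a pathlength
  roulette (survival 0.5 every 15 cm beyond 35 cm, compensated through the
  statistical weight) terminates long wanderers unbiasedly; the energy-audit
  test runs with roulette disabled.
* **RNG.** Counter-based per-photon streams (splitmix64-seeded
  xoroshiro128+), so runs are bit-reproducible for a given seed regardless of
  batching.
* **Surfaces.** Boundary normals are voxel-face normals: flat-slab physics is
  exact; curved synthetic heads are stair-step approximated (as in standard
  voxel MC codes), which distorts exit angles slightly — spherical models are
  supported for geometry and probe placement, while the quantitative physics
  oracles all run on flat slabs.

## Lookup table, NA conversion, and surrogate

`build_lookup_table()` runs one white-MC simulation per $\mu_s'$ combination
on a per-compartment node grid; the published construction uses 13 scalp, 9
skull, 4 CSF, and 6 gray-matter nodes (2808 combinations) with $10^9$ photons
per node; desk-scale studies here use 36–100 nodes at $10^4$–$10^6$ photons.
Reflectance between nodes is obtained by separable cubic-spline interpolation
of log-reflectance (`interpolate_reflectance()`); the log scale is essential
because reflectance spans decades across SDS. Interpolation is exact at the
nodes and refuses to extrapolate outside the grid hull.

Because simulating with NA = 1 collects vastly more photons than the physical
NA = 0.12 fibers, `fit_na_conversion()` regresses the low/high-NA reflectance
ratio on six features (log reflectance, log detected count, scalp/skull
$\mu_a$ and $\mu_s'$), pooled across detectors; predictions are clipped into
$(0, 1]$. The $\mu_a$ features are computed from the Beer–Lambert-rescaled
reflectance at the sampled absorption, matching the model's stated inputs
even though the underlying white simulations are absorption-free.

`generate_training_set()` pairs every grid node plus randomly interpolated
scattering combinations with random absorption combinations (white matter
coupled to gray matter) and splits rows 75/10/15 into train/validation/test.
At the published scale this is $(2808 + 3000) \times 3000 = 17.4$ million
rows. `train_surrogate()` fits a fully connected network (tanh hidden layers,
linear output on log-reflectance, z-scored inputs/outputs, minibatch Adam,
early stopping on the validation split). The published architecture is
850/550/300/150 hidden units; desk scale uses two layers of 64, which keeps
the learned map smooth — important because the fitter differentiates through
it. The network is implemented directly in the package (dense linear algebra;
an analytic vector-Jacobian product is exposed through
`surrogate_forward()`), and predictions are vectorized at well over $10^4$
queries per second on one CPU.

## Inverse problem

`fit_multistart()` minimizes the RMS percent spectral error
$$E = \sqrt{\sum_{d}\sum_{i}
  \left(\frac{R_s(d,i)}{R_m(d,i)} - 1\right)^2 / (n_d n_\lambda)}$$
over 22 wavelengths between 700 and 880 nm (sampled twice as densely below
780 nm, where hemoglobin contrast concentrates; the published work uses 22
unevenly spaced wavelengths without listing them). Initial values come from a
pre-simulated pool of feasible random parameter sets (published scale: 5000;
the 20 pool members with the smallest spectral error to the target seed 20
independent L-BFGS-B runs in unit-scaled parameter space). The
optical-property range constraint enters as a smooth quadratic hinge penalty;
a feasibility flag on each result reports whether the returned optimum
violates any range. The optimizer uses analytic gradients assembled by
backpropagating the spectral error through the surrogate and chaining through
the chromophore/power-law parameterization (verified against finite
differences in the tests). L-BFGS-B with a penalty stands in for the
published SQP routine; any bound-constrained quasi-Newton method serves.

Measurement noise makes fits within the instrument noise level (2%,
estimated from static phantom measurements) indistinguishable, so
`select_solutions()` applies the two-stage rule: keep results within 2%
(absolute, in spectral-error units) of the minimum on the fitted detectors,
then re-rank the survivors on held-out tie-breaker detectors and keep those
within 2% of that stage's minimum; two or more final survivors are flagged as
multiple solutions.

## Uncertainty quantification

`generate_test_spectra()` draws random feasible tissue-parameter sets,
simulates noiseless spectra with the surrogate, and multiplies independent
mean-one lognormal noise with the per-SDS coefficients of variation measured
in vivo (3.0, 4.2, 5.1, 5.2, 5.4, 12.1% at 0.8–4.5 cm); the published design
is 15 parameter sets × 14 noise sets = 210 noisy spectra per subject. Whether
that noise is wavelength-correlated is not stated; both modes are provided
(`correlated=`), with independent noise as the default.
`compile_confidence_intervals()` pools relative OP errors over fits (multiple
solutions as separate points) and reports empirical central 68%/95%
intervals. `rank_validation()` min-max-normalizes each target's 20 per-start
OP errors and pools them by spectral-error rank — if picking the smallest
spectral error is sound, the pooled error must grow with rank.
`sensitivity_analysis()` reports central-difference relative sensitivities of
each detector to each OP: short separations see scalp, gray-matter
sensitivity grows with separation, and gray-matter scattering is the least
determined quantity — which is why its confidence interval is the widest.

## The phantom recovery study

`phantom_recovery_study()` exercises the whole chain: a three-layer slab
(4 mm scalp-like, 6 mm skull-like, semi-infinite gray-matter-like; layer
properties from the chromophore parameterization inside the allowed ranges)
is simulated with the *absorbing* MC engine at 22 wavelengths to create
target spectra, then inverted with the lookup-table/surrogate forward and
20-start fitting, and the per-OP relative errors against ground truth are
reported. Desk-scale defaults: a 4 × 3 × 3 node grid at $7\times10^4$ photons
per node, $6\times10^4$ photons per target wavelength, four detectors at
0.8–3 cm
(the two longest separations of the six-fiber layout are too
shot-noise-limited at this photon budget to constrain anything, and a
tie-breaker stage driven by such a noisy channel was found to select *worse*
solutions), a 64+64 surrogate, and a pool of 1200. The study runs in minutes
on one CPU (the photon budgets are the knobs to turn for accuracy); all
randomness derives from one seed.

What this study shows — and what it does not: the synthetic phantom has
perfectly homogeneous layers, exactly known geometry, no instrument response,
and noise only from photon statistics. Real heads add segmentation error,
curved and inhomogeneous layers, probe-coupling drift, and calibration error.
Conversely, the full-scale pipeline enjoys $10^9$ photons per lookup node
where the desk-scale study has $\sim 10^5$: the lookup-table statistical
error at the 3 cm detector (several percent, systematic across wavelengths
because the same records underlie every query) is the desk study's dominant
error source. Superficial-layer properties are recovered to within a few
percent; the deep-layer scattering coefficient, whose log-reflectance
sensitivity at 3 cm is only $\sim 0.15$, amplifies that forward-model error
by a factor of 5–10 and can therefore carry errors of tens of percent at
desk scale. This mirrors the in-vivo finding that the gray-matter scattering
coefficient is the one quantity CW measurements determine poorly.

## Known limitations

* Radial detection (and hence the desk-scale lookup table) requires a flat
  slab; curved-model quantification would need discrete detection at much
  larger photon budgets.
* The scalp is a single homogeneous layer — no epidermis/dermis split, no
  melanin depth profile — which is one reason scalp scattering estimated from
  real foreheads tends to disagree with ex-vivo tabulations.
* The anisotropy factor is fixed at 0.9 with a Henyey–Greenstein phase
  function; sub-diffusive phase-function effects at the shortest SDS are not
  modeled.
* The synthetic chromophore tables approximate, but are not, the published
  tabulations; absolute in-vivo work must supply measured spectra.
* Eight-dimensional interpolation of the lookup table is available as a
  benchmark forward model but is slower and, at long SDS, less accurate than
  the surrogate — consistent with its published comparison.
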