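---
title: "Two-site exchange dynamics: models, fitting strategy, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site exchange dynamics: models, fitting strategy, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kexdyn)
```

# The model

`kexdyn` analyzes protein backbone dynamics through a two-site chemical
exchange model.  A ground conformational state (state 2, population
$p_2 = 1 - p_1$) interconverts with a sparsely populated excited state
(state 1, population $p_1$) through microscopic rate constants $k_{21}$
(ground to excited) and $k_{12}$ (excited to ground).  The global
parameters are

$$k_\mathrm{ex} = k_{21} + k_{12}, \qquad p_1 = k_{21}/k_\mathrm{ex},$$

shared by every residue, while each residue contributes a signed chemical
shift difference $\Delta\varpi$ (ppm, per nucleus; positive means the
excited state is downfield) and intrinsic relaxation rates.  Detailed
balance $p_1 k_{12} = p_2 k_{21}$ holds identically in this
parametrization.  The motivating system is the 169-residue G-domain of a
small GTPase whose Switch I, Switch II and P-loop regions exchange
between an ordered ground state and a partially disordered excited
state; the region presets (`gtpase_regions()`) encode those boundaries.

By default both states share each residue's intrinsic $R_1$ and $R_2$.
This is the standard identifiability constraint for sparse dispersion
data: with a minor state below ~10%, a state-specific $R_2$ trades off
almost perfectly against $\Delta\varpi$ and $k_\mathrm{ex}$.  The
`residue_spin_params()` constructor accepts explicit excited-state
overrides for users who have the data to support them.

# Forward physics

## CPMG relaxation dispersion

`simulate_cpmg()` propagates in-phase single-spin transverse
magnetization through explicit spin-echo blocks: free precession under
the complex two-site evolution matrix, with ideal 180-degree pulses
applied as complex conjugation.  Scalar-coupling and
relaxation-compensation details of real pulse sequences are absorbed
into the effective $R_2$, which is what those sequence elements are
designed to justify.

The timing convention is the standard one: at CPMG frequency
$\nu_\mathrm{CPMG}$ the echo delay is $\tau = 1/(4\nu_\mathrm{CPMG})$,
refocusing pulses are spaced $2\tau$ apart, and
$\nu_\mathrm{CPMG} \cdot T_\mathrm{relax}$ must be a whole number of
two-echo cycles.

Two read-outs are provided and it matters which one is used where:

* **`detection = "endpoint"`** (default) converts the ground-state
  amplitude that survives the constant relaxation delay into
  $R_{2,\mathrm{eff}} = -\ln(I/I_0)/T_\mathrm{relax}$.  This is what a
  spectrometer measures and is the quantity fitted against data.
* **`detection = "dominant"`** returns the decay rate of the slowest
  eigenmode of the cycle propagator.  This is the quantity the
  Carver-Richards closed form describes (we verified numerically that
  the Davis-form expression is that eigenvalue to machine precision),
  and it is the right object for closed-form cross-checks.  In slow
  exchange the two differ by up to tens of percent because the minor,
  fast-decaying mode still contributes amplitude at the end of the
  relaxation delay; this is a physical effect, not a numerical error.

## CEST

`simulate_cest()` evolves the six-dimensional magnetization (x, y, z per
state) plus longitudinal recovery under continuous $B_1$ irradiation for
the mixing time (default 150 ms), one matrix exponential per offset.
Initial magnetization is equilibrium z-magnetization partitioned by the
state populations, the standard saturation-transfer preparation.  The
profile is the ground-state z-magnetization normalized to its
equilibrium value: a major dip at the ground shift, and a minor dip at
$\Omega + \Delta\varpi$ whose side resolves the sign of
$\Delta\varpi$ that CPMG alone cannot determine.  On resonance with
$B_1$ of a few tens of Hz the magnetization nutates coherently, so
normalized intensities can dip slightly below zero; profiles are
reported unclipped.  Default $B_1$ values are 12.5 and 25 Hz,
configurable per schedule.

## Model-free relaxation rates

`lipari_szabo_rates()` evaluates the standard dipolar (N-H, 1.02
Angstrom) plus axially symmetric 15N CSA (-160 ppm) expressions on the
model-free spectral density
$J(\omega) = \tfrac{2}{5}\left[S^2\tau_c/(1+(\omega\tau_c)^2) +
(1-S^2)\tau/(1+(\omega\tau)^2)\right]$ with
$\tau^{-1} = \tau_c^{-1} + \tau_e^{-1}$.  These serve as a calibration
reference and as the physical backbone of the synthetic relaxation
generator.

# The global fit

The least-squares problem is separable: for fixed $(k_\mathrm{ex},
p_1)$, each residue's local parameters (shift differences per nucleus,
$R_2$ per nucleus and field, and for CEST residues the ground shift and
$R_1$) are independent.  `fit_global_two_state()` therefore profiles
the globals: an outer Nelder-Mead search moves $(\log k_\mathrm{ex},
\mathrm{logit}\, p_1)$, and at each step small Levenberg-Marquardt
subfits (via `minpack.lm`) solve every residue's local problem,
warm-started from the previous outer step.  A multi-start grid
(log-spaced $k_\mathrm{ex}$ over 50-3000 s$^{-1}$ crossed with $p_1 \in
\{0.02, 0.05, 0.1, 0.2\}$) guards against the local minima that plague
dispersion fitting, and the best start seeds the refinement, so the
objective never increases across restarts.

Residues enter the fit through an exchange-amplitude filter:
$R_\mathrm{ex} = R_{2,\mathrm{eff}}(\nu_\mathrm{min}) -
R_{2,\mathrm{eff}}(\nu_\mathrm{max}) > 5\ \mathrm{s}^{-1}$ by default.
CEST data fix the sign of the nitrogen $\Delta\varpi$; CPMG-only
residues report $|\Delta\varpi|$ with `sign_determined = FALSE` rather
than an arbitrary sign.  Amide-proton dispersions reuse the same engine
with the proton's own $\Delta\varpi_{HN}$ (reported unsigned).  Per-field
$R_2$ nuisance parameters are fitted independently at each static field.

Uncertainties come from a residue-level bootstrap
(`bootstrap_uncertainties()`): residues are resampled with replacement,
keeping each residue's profile intact to preserve within-profile
correlation, and the globals are refit per replicate warm-started from
the converged solution.  The replicate spread gives the standard
deviations, percentile intervals and the $(k_\mathrm{ex}, p_1)$
covariance used by `derived_rates()` for first-order error propagation
onto $k_{21}$ and $k_{12}$.  Because the inner solves do not depend on
the resample weights, warm caches make the 50-100 replicate default
affordable.

A two-state fit applied to effectively single-state data either raises a
selection error (nothing passes the $R_\mathrm{ex}$ filter) or returns a
result flagged `non_identifiable`; it does not manufacture a confident
excited-state population.

## Numerical choices

* Outer convergence: relative tolerance $10^{-7}$ on the profiled
  objective, up to 120 Nelder-Mead iterations after the grid stage;
  inner subfits run at tolerance $10^{-6}$ while profiling and
  $10^{-8}$ at the final solve.
* CPMG propagators use a closed-form complex 2x2 matrix exponential;
  CEST uses a dense 7x7 exponential (homogeneous augmentation of the
  recovery term) per offset, in compiled code.
* Bounds: $|\Delta\varpi_N| \le 12$ ppm, $\Delta\varpi_{HN} \in [0,3]$
  ppm, rates positive; box constraints are enforced by the
  Levenberg-Marquardt solver.
* Cold starts read the data: $R_2$ from the fastest-pulsing point,
  $\Delta\varpi$ from the dispersion amplitude (fast-exchange inversion,
  capped), the CEST ground shift from the deepest dip and the signed
  $\Delta\varpi$ guess from the deepest dip away from it.

# NASR order parameters

Transient adsorption to slowly tumbling nanoparticles amplifies
transverse relaxation in proportion to the angular restriction of each
N-H vector.  The package reduces the published nanoparticle-relaxation
formalism to its operational core: $\Delta R_2 = R_2^{+NP} - R_2^{-NP}$
maps onto $S^2 = \Delta R_2 / \lambda$ with a single global scale
$\lambda$.  Two calibrations are provided because the original
normalization protocol is not fully specified by the source material:
error-weighted regression against a reference $S^2$ profile over rigid
(regular secondary structure) residues, and a reference-free mode where
$\lambda$ is the mean of the top decile of $\Delta R_2$ so the most
rigid residues map near 1.  Negative $\Delta R_2$ beyond $3\sigma$ is
flagged as a possible nanoparticle-binding anomaly and excluded from
calibration, but never clipped from the output profile: clipping would
bias dynamics detection.  `monte_carlo_errors()` resamples all rates
from their Gaussian error models and repeats the entire mapping,
including $\lambda$ re-estimation, per draw.

# Ensemble order parameters and population fitting

For unit N-H vectors $\hat e^{(k)}$ with weights $w_k$,

$$S^2 = \frac{3}{2}\sum_{a,b}\Big(\sum_k w_k\, e_a^{(k)} e_b^{(k)}\Big)^2 - \frac{1}{2},$$

the second-rank orientational tensor contraction, algebraically equal to
the pair-sum $\sum_{jk} w_j w_k P_2(\hat e^{(j)}\cdot\hat e^{(k)})$ that
the test suite uses as a brute-force oracle.  Conformers are first
superposed (Kabsch/SVD) over backbone atoms outside the mobile regions
and termini, so Switch motion does not bias the common frame — the
source analyses do not state their frame, and this is the choice that
makes the order parameter reflect internal motion rather than alignment
error.  Amide hydrogens, absent from crystal structures, are built at
1.02 Angstrom along the bisector of the external C(i-1)-N-CA angle;
prolines and chain N-termini are skipped.  No librational scaling factor
is applied to the ensemble $S^2$ (none is stated in the source
analyses); any uniform fast-libration factor would scale all residues
alike and can be applied downstream.

`fit_populations()` searches the weight simplex exhaustively at 1%
resolution — chosen over purely continuous optimization so that
near-degenerate weight sets are visible in the reported top-10 table —
then refines continuously from the grid optimum.  The objective is the
RMSD between back-calculated and experimental $S^2$ over a residue mask
(by default everything shared; for GTPase work the Switch regions plus
flanks).

# The synthetic-data generator

`truth_spec()` / `generate_observations()` emulate the statistical
structure the analysis assumes: globally shared $(k_\mathrm{ex}, p_1)$;
$|\Delta\varpi_N|$ uniform on 1-5 ppm (and $|\Delta\varpi_{HN}|$ on
0.1-0.6 ppm) with random signs inside designated Switch-like and
P-loop-like regions, below 0.3 ppm outside; intrinsic $R_2$ uniform on
12-20 s$^{-1}$; 2% relative Gaussian noise on CPMG amplitudes
(propagated through the log into $R_{2,\mathrm{eff}}$ and its error) and
2% absolute noise on normalized CEST intensities.  The standard study
design used by the end-to-end checks is a 25-residue chain with a
10-residue exchange region: nitrogen CPMG at 850 and 600 MHz and proton
CPMG at 850 MHz (40 ms relaxation delay, 12 frequencies from 25 to
1000 Hz), plus a nitrogen CEST plane at 850 MHz (150 ms, $B_1$ = 25 Hz,
1 ppm offset grid) for the first six exchange residues.  These sizes are
the package's reference workload; they keep a full
fit-plus-50-replicate-bootstrap run of all three variant studies in the
minutes range on a single core.

What the generator does *not* emulate — and therefore what passing
recovery tests do and do not show — includes: peak overlap and
assignment ambiguity, temperature and buffer effects, $B_1$
inhomogeneity and off-resonance pulse imperfections, three-site or
temperature-dependent exchange, correlated (non-Gaussian) noise, and
nanoparticle-concentration dependence in NASR.  Recovery on synthetic
data demonstrates that the estimator is consistent and well-calibrated
under the stated model, not that real spectra are free of these
systematics.

The NASR generator draws a rigid baseline ($S^2 \approx 0.85$) with
floppy termini and designated low-$S^2$ dips (Switch II-like dips in
0.21-0.37), produces nanoparticle-free rates from the model-free
expressions at $\tau_c$ = 10 ns, and adds $\Delta R_2 = \lambda S^2$
with $\lambda = 30\ \mathrm{s}^{-1}$, a scale typical of silica
nanoparticle experiments at sub-micromolar particle concentrations.
The toy-ensemble generator builds ideal polyalanine backbones and
rotates designated N-H vectors by specified angles, so the exact
$S^2$ truth is available from the pair-sum closed form.

# Known limitations

* Exchange models beyond two sites, off-resonance $R_{1\rho}$, TROSY
  selection and nucleotide phosphorus NMR are out of scope.
* The NASR mapping is linear by construction; genuine nanoparticle
  binding-kinetics effects (particle size, concentration) are not
  modeled.
* The equilibrium-parameter arithmetic treats published rate pairs as
  exact inputs; their printed rounding propagates into derived values.
* NMR-STAR support covers the assigned chemical-shift loop only, which
  is the part needed to consume deposition files as shift tables.
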