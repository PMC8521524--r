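---
title: "Models and methods: arginine salt bridges in disordered amyloid-beta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: arginine salt bridges in disordered amyloid-beta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absalt)
```

The N-terminus of amyloid-beta (1-40) is intrinsically disordered, yet its
single arginine (Arg5) transiently forms salt bridges with nearby aspartate
and glutamate side chains (Asp1, Glu3, Asp7, Glu11). These contacts are weak
and populated only in a fraction of the conformational ensemble, so no
single experiment sees them directly; they are inferred jointly from
high-pressure NMR, conformer-ensemble geometry, guanidinium exchange
dynamics, and phosphorylation energetics. `absalt` implements each of those
four analyses and a synthetic-data module that generates all the inputs with
known ground truth. This vignette explains the models, the tunable
parameters, and the numerical and design choices, in the package's own
terms.

## Pressure response of chemical shifts

Hydrostatic pressure pushes a conformational ensemble toward its
lower-volume members, and chemical shifts follow. Each (residue, nucleus)
shift series measured across a pressure ladder (defaults 1, 500, 1000,
1500, 2000 bar) is fitted by ordinary least squares to a second-order
Taylor expansion about the ambient reference pressure $p_0 = 1$ bar:

$$\delta(p) = \delta_0 + B_1\,\frac{p - p_0}{1000} + B_2\left(\frac{p - p_0}{1000}\right)^2,$$

with pressures in bar, so $B_1$ is in ppm/kbar and $B_2$ in ppm/kbar².
`fit_pressure_coefficients()` returns the coefficients with standard errors
computed from the unscaled covariance of the linear model (the standard
errors are undefined when the point count equals the parameter count, where
the fit interpolates exactly). A linear-only mode (`order = 1`) is provided
because in practice $B_1$ carries most of the structural signal; it fixes
$B_2 = 0$.

Part of any residue's pressure response is generic to unstructured chains.
`apply_random_coil_correction()` subtracts per-(residue type, nucleus)
reference coefficients measured on random-coil model peptides. Two choices
here were genuinely open:

* **Correction acts on coefficients, not raw shifts.** For polynomial
  models the two are algebraically identical, and coefficient subtraction
  is easier to audit.
* **Both $B_1$ and $B_2$ are corrected.** The reference table carries
  `B1_rc` and `B2_rc` columns, so users who prefer to correct only the
  linear term can zero the `B2_rc` column.

No published per-residue random-coil table is bundled: the shipped default
reference is empty, every lookup falls back to a zero correction, and the
result is flagged `rc_missing` so that "corrected" values are never
silently mistaken for truly referenced ones. The CSV at
`system.file("extdata", "random_coil_reference.csv", package = "absalt")`
is the template for supplying measured values.

`classify_response()` labels residues `positive` / `negative` / `near_zero`
by comparing the corrected $B_1$ against a magnitude threshold. The
threshold has no canonical literature value; the default 0.2 ppm/kbar is a
practical choice for backbone ¹⁵N coefficients, where structural responses
of interest are several tenths of a ppm/kbar, and it is exposed as a
parameter. `fit_intensity_trend()` fits the complementary observable — a
linear intensity-versus-pressure slope per kbar, used for side-chain peaks
whose intensity grows as pressure dissolves an exchange-broadening salt
bridge — with a `flat_tol` of 1e-8 by default so only numerically constant
series are labelled flat.

## Salt-bridge geometry over conformer ensembles

A guanidinium group can engage a carboxylate in three modes: two bidentate
geometries — *side-on* (both terminal NH nitrogens contact distinct
oxygens) and *end-on* (NE and one NH contact distinct oxygens) — and the
monodentate *backside* contact. `classify_mode()` reduces the geometry to
the six heavy-atom N···O distances and applies:

1. side-on if NH1 and NH2 each contact a distinct oxygen;
2. else end-on if NE and one NH each contact distinct oxygens;
3. else backside if any contact remains;
4. else none.

Three decisions deserve comment. First, the **contact criterion is
heavy-atom N···O ≤ 3.5 Å** — the standard salt-bridge/hydrogen-bond
cutoff — because reduced representations and most ensemble files lack
protons; the cutoff is a parameter everywhere. Second, **precedence is
side-on > end-on > backside**: when several patterns hold simultaneously
the highest-denticity interpretation is reported, consistent with the
bidentate geometries being the lower-energy states. Third, **bidentate
modes require distinct oxygens**; two nitrogens reaching the same single
oxygen is monodentate toward that oxygen and therefore backside. With that
reading, rule 3 is exhaustive: any contact pattern in which two nitrogens
touch *different* oxygens is already captured by rules 1-2, because every
nitrogen pair (NH1/NH2, NE/NH1, NE/NH2) is a qualifying bidentate pair.
The test suite verifies the implementation against an independent
brute-force oracle over all 64 contact patterns, and checks invariance
under rigid motions, oxygen label swaps, and cutoff enlargement (a larger
cutoff can upgrade but never erase an assignment).

`scan_ensemble()` applies the classifier to every (Arg donor, Asp/Glu
acceptor) pair in every conformer, vectorised over the ensemble;
`bridge_occupancy()` reduces that to per-pair occupancies with a per-mode
breakdown that sums exactly to the occupancy, `simultaneous_bridging()`
counts conformers where one donor engages several acceptors at once, and
`conditional_ca_distance()` summarises a residue pair's Cα-Cα distance (in
nm, matching the field's convention for backbone statistics) conditioned on
bridge presence. Only side-chain carboxylates participate; the C-terminal
backbone carboxylate and N-terminal ammonium are not treated as partners.

## Two-site symmetric-exchange CEST

The guanidinium group rotates about the Cζ-Nε bond, exchanging its two Nη
nitrogens between two magnetically distinct environments with equal
populations. Saturation transfer (CEST) reads this out: irradiating at one
Nη resonance depletes the other through exchange, producing intensity dips.

`simulate_cest_profile()` propagates the six-component magnetisation
(x, y, z for each site) under the Bloch-McConnell generator — transverse
relaxation $R_2$, longitudinal relaxation $R_1$ toward equilibrium,
nutation by the saturation field $\omega_1 = 2\pi B_1$, offset precession,
and symmetric exchange at rate $k_\mathrm{ex}/2$ per direction — for the
saturation time $T_\mathrm{sat}$, and reports total z-magnetisation
normalised to the no-saturation reference. The propagator is evaluated by
eigendecomposition of the (augmented, 7×7) generator, with a
scaling-and-squaring matrix exponential as fallback when the eigenbasis is
ill-conditioned; this is numerically stable across the full offset range,
where naive Padé evaluation of the stiff generator can overflow.

Conventions, stated explicitly because the CEST literature is split:

* **$k_\mathrm{ex}$ is the sum of forward and backward rates** (each
  direction runs at $k_\mathrm{ex}/2$); populations are fixed at 0.5/0.5
  by the symmetry of rotational exchange.
* **$\Delta\omega$ is in rad/s**, converted to ppm through the configured
  nitrogen Larmor frequency (default 81.1 MHz), which is recorded in every
  model object and fit output.

This is deliberately a *longitudinal two-site stand-in* for the
multiquantum CEST experiment that motivates it: the multiquantum coherence
pathway is not simulated. Round-trip analyses (simulate with the model, fit
with the model) are valid for any acquisition parameters; conclusions about
real multiquantum data would additionally require the pulse-sequence-level
model, which is out of scope. Acquisition defaults — $B_1$ 25 Hz,
$T_\mathrm{sat}$ 0.4 s, $R_1$ 1.5 s⁻¹, $R_2$ 30 s⁻¹ — are plausible values
for a slow-tumbling disordered peptide at low temperature and are all
configurable; none of the package's validation results depend on the
specific choice.

`fit_cest_profile()` runs Levenberg-Marquardt least squares over
$(k_\mathrm{ex}, \Delta\omega, \mathrm{center})$ from a multi-start grid
(defaults $k_\mathrm{ex} \in \{50, 200, 500, 1000\}$ s⁻¹ ×
$\Delta\omega \in \{500, 1000, 2000\}$ rad/s; centre started at the profile
minimum), keeps the best converged start by residual sum of squares, and
reports covariance-based standard errors plus the full multi-start log.
Profiles flatter than 0.02 in total range are rejected as carrying no
exchange information, and fewer than 8 points is an error. `detect_dips()`
finds local minima of the (optionally moving-average-smoothed) profile and
measures each dip's depth against its local baseline — the lower of the two
flanking maxima — labelling the deepest dip `major`. In the fast-exchange
limit ($k_\mathrm{ex} \gg \Delta\omega$) the two dips coalesce at the
centre shift, which the tests assert.

One physical subtlety: total z-magnetisation can transiently go slightly
negative under very strong saturation fields with short $T_\mathrm{sat}$
(underdamped nutation), so the hard positivity of intensities holds in the
continuous-wave saturation regime the module targets ($B_1 \lesssim 50$ Hz,
$T_\mathrm{sat} \gtrsim 0.2$ s) while the general bound is the profile
contract $[-0.05, 1.05]$. Both statements are tested.

## Phosphorylation energetics

`group_stats()` reproduces the group-comparison arithmetic applied to
per-conformer quantum-chemistry energy tables: per conformer
$\Delta E = E_\mathrm{phos} - E_\mathrm{nonphos}$ (hartrees), per group
mean ± sd, and each group's
$\Delta\Delta E = \overline{\Delta E}_\mathrm{group} -
\overline{\Delta E}_\mathrm{control}$ in hartrees and kJ/mol
(1 hartree = 2625.4996 kJ/mol, CODATA). A positive $\Delta\Delta E$ means
the group is relatively destabilised by phosphorylation. Note that a
kJ/mol column computed from unrounded means will not match the product of
a 3-decimal hartree column with the conversion constant (0.035 × 2625.5 ≈
91.9 while the unrounded difference can print as 90.96); similarly a
printed $\Delta\Delta E$ may differ in the last digit from the difference
of printed group means. Both are rounding artefacts, not bugs, and the
package always computes from unrounded values. No quantum chemistry is
performed: energies are consumed from CSV.

## What the synthetic data emulate — and what they do not

The generators produce every input type with machine-readable truth
attached (an R attribute, and a JSON sidecar when written to disk via
`write_synthetic_csv()` / `write_ensemble_pdb()`), and are deterministic
under a seed.

`gen_shift_table()` evaluates the quadratic pressure model exactly and adds
i.i.d. Gaussian noise — adequate for validating the fitter (exact
round-trip at zero noise; unbiased $B_1$ over 500 replicates), but it does
not emulate correlated baseline drift, exchange-broadening intensity loss,
or peak overlap of real spectra.

`gen_ensemble()` builds reduced-atom conformers: a 40-residue Cα random
walk with 3.8 Å steps and approximate self-avoidance (non-neighbour Cα
pairs kept ≥ 4 Å apart by per-step rejection with a 1000-retry budget
before the walk restarts), decorated with an idealised guanidinium on Arg5
and carboxylates on all six Asp/Glu residues. Bridges are planted by
Bernoulli draws at the configured occupancies (defaults 14%, 10%, 6%, 2%
for Asp7, Glu3, Glu11, Asp1), with planted contact distances drawn from
2.8-3.2 Å, safely inside the 3.5 Å detection cutoff. Two generator-level
subtleties matter for correctness:

* **The double-bridge fraction is a joint law, not a flag.** The default
  0.3% simultaneous Glu3+Asp7 fraction is *below* the ≈1.4% that
  independent draws at the marginal occupancies would produce, so the two
  acceptors are drawn from an explicitly anti-correlated four-cell joint
  distribution that realises the joint fraction exactly while preserving
  both marginals. Infeasible combinations (joint above a marginal, or
  marginals plus joint exceeding 1) are rejected with an error naming the
  conflict.
* **Unbridged carboxylates are kept clear of the guanidinium** (placement
  is resampled until all N···O distances exceed 4 Å, with a guaranteed
  far-placement fallback), so detected occupancy equals planted occupancy
  rather than planted-plus-accidental. The tests assert exact
  planted-versus-detected agreement per conformer.

Bridge-coupled compaction is emulated by redrawing the Glu3-Ser8 Cα
distance from N(1.25, 0.05) nm when an Arg5-Glu3 or Arg5-Asp7 bridge is
present and N(1.39, 0.05) nm otherwise, implemented by translating the
Ser8 Cα along the existing axis (which locally distorts the two adjacent
virtual bonds — accepted, since the walk is a scaffold, not a physical
chain model). These ensembles are geometric scaffolds with correct *count
statistics*; they are not force-field ensembles and carry no physical
energetics, secondary structure, or realistic side-chain packing, so
passing recovery tests demonstrates estimator correctness, not anything
about real amyloid-beta conformers.

`gen_cest_profile()` adds i.i.d. Gaussian noise to an exact simulation
(real CEST noise is closer to multiplicative and correlated across
offsets); `gen_energy_table()` draws per-conformer $\Delta E$ from Gaussian
group laws around an arbitrary baseline that cancels in all statistics.

## Problem sizes and numerical tolerances

The validation suite uses ensembles of 500-20 000 conformers (20 000 for
the 0.3% double-bridge fraction, where a 2σ binomial band at 5 000
conformers would span more than half the target value), 121-point CEST
profiles for round-trip fits, 25-point profiles for the 200-replicate
confidence-interval calibration (covering 95% nominal intervals within
[0.90, 0.99]), and 500-replicate unbiasedness checks for the pressure
fitter. Stochastic recovery checks use binomial 2σ or 3·SEM bands at the
stated sizes. Fit convergence follows `minpack.lm` defaults with a 200
iteration cap per start; ties between converged starts resolve to the
lowest residual sum of squares.

## Known limitations

* The CEST module is a longitudinal stand-in for a multiquantum
  experiment; two-species (salt-bridged vs free) exchange fitting is
  deliberately not attempted — a minor dip's position can be detected, but
  its population and rates are not identifiable from these profiles.
* The mode classifier follows the bidentate/monodentate geometric
  definitions given above; published analyses built on other geometric
  conventions (e.g. hydrogen-position criteria) may partition borderline
  conformers differently.
* The empty default random-coil reference means "corrected" coefficients
  equal raw ones until the user supplies a measured table.
* Ensembles are single-chain: intermolecular bridges in oligomers are out
  of scope.
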