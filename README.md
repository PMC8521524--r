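# absalt

Transient arginine salt bridges in the disordered N-terminus of
amyloid-beta (1-40) — the contacts Arg5 makes with Asp1, Glu3, Asp7 and
Glu11 — are populated in only a minority of conformers, so characterising
them requires combining several indirect readouts. `absalt` is an R package
for researchers doing exactly that: it implements the four analyses
typically run together on such systems, plus a seeded synthetic-data module
that generates every input type with known ground truth for validation.

1. **Pressure-response fitting.** Chemical shifts measured across a
   hydrostatic-pressure ladder are fitted to a second-order Taylor
   expansion, δ(p) = δ₀ + B₁(p−p₀)/1000 + B₂((p−p₀)/1000)², giving
   first/second-order pressure coefficients (ppm/kbar, ppm/kbar²) that are
   corrected against a random-coil reference and classified as
   positive / negative / near-zero responses.
2. **Salt-bridge geometry.** Guanidinium-carboxylate contacts in a
   multi-conformer ensemble are classified into *side-on* and *end-on*
   (bidentate: two nitrogens on distinct oxygens) and *backside*
   (monodentate) modes from heavy-atom N···O distances (default cutoff
   3.5 Å), with ensemble occupancies, simultaneous-bridging fractions, and
   bridge-conditional Cα-Cα distance statistics.
3. **CEST exchange modelling.** Saturation-transfer profiles of the two
   guanidinium Nη nuclei are simulated and fitted under a two-site
   symmetric-exchange Bloch-McConnell model (equal populations; k_ex is
   the sum of forward and backward rates), recovering k_ex (s⁻¹) and
   Δω (rad/s) by multi-start Levenberg-Marquardt least squares, with dip
   detection for major/minor exchange species.
4. **Phosphorylation energetics.** Per-conformer energy differences
   ΔE = E_phos − E_nonphos are summarised per conformer group and compared
   against a control group as ΔΔE, in hartrees and kJ/mol
   (1 hartree = 2625.4996 kJ/mol).

All user-facing functions take a data frame first and return tibbles, so
analyses compose with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(absalt)

# --- pressure coefficients from a synthetic shift table ---------------
shifts <- gen_shift_table(seed = 101, noise_sd = 0.01)
coefs <- shifts |>
  fit_pressure_coefficients() |>        # quadratic fit, p0 = 1 bar
  apply_random_coil_correction() |>     # empty default table: flags rc_missing
  classify_response(threshold = 0.2)
dplyr::select(coefs, residue_index, residue_name, B1, B1_se, response)
#>   residue_index residue_name      B1  B1_se response
#> 1             3 GLU           0.449  0.0150 positive
#> 2             5 ARG          -0.808  0.0149 negative
#> 3             6 HIS          -0.654  0.0339 negative
#> 4             7 ASP           0.559  0.0131 positive
#> ...
```

`B1` is the linear pressure coefficient in ppm/kbar; Arg5 and the
histidines respond negatively (their environment is lost under pressure),
while Glu3/Asp7 respond positively — the mixed-sign pattern characteristic
of a pressure-sensitive contact network.

```r
# --- salt-bridge occupancies in a 2000-conformer ensemble -------------
ens <- gen_ensemble(2000, seed = 101)   # plants bridges at 14/10/6/2 %
occ <- bridge_occupancy(scan_ensemble(ens, cutoff = 3.5))
dplyr::select(occ, acceptor, acceptor_name, occupancy, f_side_on)
#>   acceptor acceptor_name occupancy f_side_on
#> 1        1 ASP              0.017     0.017
#> 2        3 GLU              0.110     0.108
#> 3        7 ASP              0.134     0.134
#> 4       11 GLU              0.0575    0.0575
#> 5       22 GLU              0         0
#> 6       23 ASP              0         0
```

Occupancy is the fraction of conformers in which Arg5 engages that
acceptor; the planted 14% / 10% / 6% / 2% rates are recovered within
binomial sampling noise, and the distant acceptors Glu22/Asp23 are never
hit.

```r
# --- CEST round trip on the free-arginine reference parameters --------
profile <- simulate_cest_profile(
  exchange_model(k_ex = 356, delta_omega = 1214),
  seq(60, 90, by = 0.25)
)
fit_cest_profile(profile)
#> Two-site symmetric-exchange CEST fit
#>   k_ex        356 +/- 1.8e-11 1/s
#>   delta_omega 1214 +/- 1.2e-11 rad/s
#>   center      71.0000 ppm
#>   rss 1.33e-26 over 121 points; 12/12 starts converged
#>   k_ex is the sum of forward and backward rates; delta_omega in rad/s
```

The multi-start fitter recovers the generating rotational exchange rate
and Nη shift difference exactly from a noiseless profile.

```r
# --- phosphorylation energetics ---------------------------------------
group_stats(gen_energy_table(seed = 101))
#>   group                 n mean_dE  sd_dE ddE_hartree ddE_kjmol is_control
#> 1 test_both_bridges     7   -567. 0.0400      0.0624     164.  FALSE
#> 2 test_d7_only          8   -567. 0.0242      0.0222      58.2 FALSE
#> 3 control              12   -567. 0.0206      0            0   TRUE
```

Positive `ddE_hartree` means the group is relatively destabilised by Ser8
phosphorylation compared with the bridge-free control group (here, sample
means from small synthetic groups drawn around the configured laws).

See the vignette (`vignettes/salt-bridge-methods.Rmd`) for the models,
conventions, default parameters, and what the synthetic data do and do not
emulate.

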