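# Random-coil reference pressure coefficients, per residue type and nucleus.
# B1_rc in ppm/kbar, B2_rc in ppm/kbar^2, to be SUBTRACTED from fitted
# coefficients by apply_random_coil_correction().
# The shipped default is deliberately empty: no published per-residue table is
# bundled, so every lookup falls back to (0, 0) and is flagged rc_missing.
# Replace this file (or pass your own CSV) with measured reference values,
# one row per (residue_name, nucleus), e.g.:
# ALA,N,0.46,-0.22
residue_name,nucleus,B1_rc,B2_rc
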