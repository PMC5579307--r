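# Reference binary system: IR3535 (A) / nonanoic acid (B) at 50 C.
# Phenomenological stand-in calibrated so the two activity-ratio crossings
# (the azeotropes) fall at exactly 10 and 77 mol% IR3535 at 323.15 K, with
# the 77 mol% root at the bubble-pressure minimum, the 10 mol% root at the
# maximum, and the liquid locally stable (1 + x(1-x) g'' > 0) at every
# composition. No measured VLE data exist for this system.
temperature_K: 323.15
component_a:
  name: IR3535
  molar_mass_g_mol: 215.29
  molar_volume_mL_mol: 215.7
  antoine: [29.803, 9500.0, 0.0]      # ln P[Pa] = A - B/(T[K] + C)
  t_range_K: [283.15, 373.15]
component_b:
  name: nonanoic acid
  molar_mass_g_mol: 158.24
  molar_volume_mL_mol: 174.7
  antoine: [26.8490080457992, 8400.0, 0.0]
  t_range_K: [283.15, 373.15]
activity_coefficients: [-0.36301120263033, -1.73241590060769, 0.701735687141687,
                        2.59306719358183, -0.121811612607676, -3.22186980093564,
                        -0.36691287734469, 1.46121850682536]
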