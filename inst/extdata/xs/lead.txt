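# Linear photon attenuation coefficients for lead (1/cm), density 11.35 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.000e+01 1.338965e+03 1.732283e+00 1.416124e+02 1.482310e+03
1.250e+01 1.260269e+03 1.716534e+00 9.267706e+01 1.354663e+03
1.500e+01 1.199416e+03 1.701158e+00 6.554323e+01 1.266660e+03
1.750e+01 1.052924e+03 1.686142e+00 4.890226e+01 1.103512e+03
2.000e+01 9.405704e+02 1.671473e+00 3.794410e+01 9.801860e+02
2.500e+01 5.240484e+02 1.643132e+00 2.483220e+01 5.505237e+02
3.000e+01 3.249541e+02 1.616045e+00 1.756187e+01 3.441320e+02
3.500e+01 2.157060e+02 1.590132e+00 1.310304e+01 2.303991e+02
4.000e+01 1.512538e+02 1.565317e+00 1.016687e+01 1.629860e+02
4.500e+01 1.102540e+02 1.541531e+00 8.128258e+00 1.199238e+02
5.000e+01 8.309302e+01 1.518711e+00 6.653624e+00 9.126535e+01
5.500e+01 6.425130e+01 1.496799e+00 5.551523e+00 7.129963e+01
6.000e+01 5.080702e+01 1.475741e+00 4.705588e+00 5.698835e+01
6.500e+01 4.091578e+01 1.455487e+00 4.041717e+00 4.641298e+01
7.000e+01 3.348343e+01 1.435991e+00 3.510872e+00 3.843029e+01
7.500e+01 2.778294e+01 1.417210e+00 3.079533e+00 3.227969e+01
8.000e+01 2.333240e+01 1.399105e+00 2.724145e+00 2.745565e+01
8.500e+01 1.971599e+01 1.381638e+00 2.427757e+00 2.352539e+01
8.799e+01 1.791056e+01 1.371484e+00 2.273411e+00 2.155546e+01
8.801e+01 8.302391e+01 1.371417e+00 2.272429e+00 8.666776e+01
9.000e+01 7.840423e+01 1.364776e+00 2.177913e+00 8.194692e+01
9.500e+01 6.826784e+01 1.348487e+00 1.965289e+00 7.158161e+01
1.000e+02 5.986562e+01 1.332740e+00 1.782794e+00 6.298115e+01
1.100e+02 4.671139e+01 1.302766e+00 1.487494e+00 4.950165e+01
1.200e+02 3.724350e+01 1.274652e+00 1.260831e+00 3.977898e+01
1.300e+02 3.023825e+01 1.248224e+00 1.082951e+00 3.256943e+01
1.400e+02 2.493288e+01 1.223327e+00 9.407148e-01 2.709693e+01
1.500e+02 2.083394e+01 1.199823e+00 8.251404e-01 2.285890e+01
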