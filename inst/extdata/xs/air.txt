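# Linear photon attenuation coefficients for air (1/cm), density 0.001205 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.00e+01 5.728875e-03 2.319931e-04 2.087317e-04 6.169600e-03
1.25e+01 2.859187e-03 2.298839e-04 1.366027e-04 3.225674e-03
1.50e+01 1.620437e-03 2.278246e-04 9.660843e-05 1.944870e-03
1.75e+01 9.994427e-04 2.258136e-04 7.208023e-05 1.297337e-03
2.00e+01 6.575921e-04 2.238492e-04 5.592828e-05 9.373695e-04
2.50e+01 3.262608e-04 2.200536e-04 3.660180e-05 5.829162e-04
3.00e+01 1.840173e-04 2.164261e-04 2.588559e-05 4.263290e-04
3.50e+01 1.136176e-04 2.129557e-04 1.931342e-05 3.458867e-04
4.00e+01 7.482455e-05 2.096323e-04 1.498561e-05 2.994425e-04
4.50e+01 5.191967e-05 2.064469e-04 1.198077e-05 2.703473e-04
5.00e+01 3.744200e-05 2.033908e-04 9.807209e-06 2.506400e-04
5.50e+01 2.792486e-05 2.004563e-04 8.182751e-06 2.365639e-04
6.00e+01 2.136551e-05 1.976361e-04 6.935872e-06 2.259375e-04
6.50e+01 1.673644e-05 1.949236e-04 5.957349e-06 2.176174e-04
7.00e+01 1.334983e-05 1.923127e-04 5.174902e-06 2.108374e-04
7.50e+01 1.081598e-05 1.897975e-04 4.539124e-06 2.051526e-04
8.00e+01 8.882952e-06 1.873728e-04 4.015295e-06 2.002710e-04
8.50e+01 7.418896e-06 1.850336e-04 3.578430e-06 1.960309e-04
9.00e+01 6.260275e-06 1.827753e-04 3.210167e-06 1.922458e-04
9.50e+01 5.331332e-06 1.805938e-04 2.896767e-06 1.888219e-04
1.00e+02 4.577802e-06 1.784849e-04 2.627777e-06 1.856905e-04
1.10e+02 3.520368e-06 1.744707e-04 2.192514e-06 1.801835e-04
1.20e+02 2.769819e-06 1.707056e-04 1.858421e-06 1.753339e-04
1.30e+02 2.221544e-06 1.671663e-04 1.596232e-06 1.709841e-04
1.40e+02 1.811178e-06 1.638319e-04 1.386581e-06 1.670297e-04
1.50e+02 1.497577e-06 1.606842e-04 1.216228e-06 1.633980e-04
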