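# Linear photon attenuation coefficients for water (1/cm), density 1 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.00e+01 4.932653e+00 2.141092e-01 1.822380e-01 5.329000e+00
1.25e+01 2.445418e+00 2.121626e-01 1.192641e-01 2.776845e+00
1.50e+01 1.378392e+00 2.102621e-01 8.434618e-02 1.673000e+00
1.75e+01 8.459199e-01 2.084061e-01 6.293127e-02 1.117257e+00
2.00e+01 5.541774e-01 2.065931e-01 4.882945e-02 8.096000e-01
2.50e+01 2.731710e-01 2.030902e-01 3.195603e-02 5.082172e-01
3.00e+01 1.532577e-01 1.997423e-01 2.260000e-02 3.756000e-01
3.50e+01 9.415862e-02 1.965394e-01 1.686202e-02 3.075600e-01
4.00e+01 6.174424e-02 1.934722e-01 1.308353e-02 2.683000e-01
4.50e+01 4.264475e-02 1.905323e-01 1.046008e-02 2.436372e-01
5.00e+01 3.062577e-02 1.877118e-01 8.562406e-03 2.269000e-01
5.50e+01 2.281916e-02 1.850035e-01 7.144136e-03 2.149668e-01
6.00e+01 1.744371e-02 1.824008e-01 6.055520e-03 2.059000e-01
6.50e+01 1.367133e-02 1.798974e-01 5.201199e-03 1.987699e-01
7.00e+01 1.091012e-02 1.774877e-01 4.518066e-03 1.929159e-01
7.50e+01 8.843228e-03 1.751664e-01 3.962985e-03 1.879726e-01
8.00e+01 7.265769e-03 1.729286e-01 3.505644e-03 1.837000e-01
8.50e+01 6.039659e-03 1.707697e-01 3.124229e-03 1.799336e-01
9.00e+01 5.073791e-03 1.686856e-01 2.802709e-03 1.765621e-01
9.50e+01 4.302745e-03 1.666722e-01 2.529088e-03 1.735040e-01
1.00e+02 3.679861e-03 1.647259e-01 2.294240e-03 1.707000e-01
1.10e+02 2.794271e-03 1.610211e-01 1.914224e-03 1.657296e-01
1.20e+02 2.173283e-03 1.575463e-01 1.622536e-03 1.613421e-01
1.30e+02 1.724669e-03 1.542798e-01 1.393627e-03 1.573981e-01
1.40e+02 1.392324e-03 1.512025e-01 1.210586e-03 1.538054e-01
1.50e+02 1.140752e-03 1.482974e-01 1.061856e-03 1.505000e-01
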