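# Linear photon attenuation coefficients for copper (1/cm), density 8.96 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.00e+01 1.914990e+03 1.577545e+00 1.789674e+01 1.934464e+03
1.25e+01 1.059884e+03 1.563203e+00 1.171237e+01 1.073159e+03
1.50e+01 6.536556e+02 1.549200e+00 8.283246e+00 6.634880e+02
1.75e+01 4.278946e+02 1.535525e+00 6.180188e+00 4.356103e+02
2.00e+01 2.964409e+02 1.522167e+00 4.795313e+00 3.027584e+02
2.50e+01 1.576919e+02 1.496357e+00 3.138253e+00 1.623265e+02
3.00e+01 9.415207e+01 1.471690e+00 2.219441e+00 9.784320e+01
3.50e+01 6.019121e+01 1.448091e+00 1.655940e+00 6.329525e+01
4.00e+01 4.085315e+01 1.425493e+00 1.284872e+00 4.356352e+01
4.50e+01 2.888863e+01 1.403832e+00 1.027236e+00 3.131970e+01
5.00e+01 2.118856e+01 1.383050e+00 8.408741e-01 2.341248e+01
5.50e+01 1.596860e+01 1.363096e+00 7.015924e-01 1.803329e+01
6.00e+01 1.233468e+01 1.343919e+00 5.946845e-01 1.427328e+01
6.50e+01 9.709013e+00 1.325474e+00 5.107855e-01 1.154527e+01
7.00e+01 7.779110e+00 1.307720e+00 4.436982e-01 9.530528e+00
7.50e+01 6.328894e+00 1.290616e+00 3.891863e-01 8.008696e+00
8.00e+01 5.218079e+00 1.274128e+00 3.442730e-01 6.836480e+00
8.50e+01 4.348846e+00 1.258222e+00 3.068160e-01 5.913884e+00
9.00e+01 3.662368e+00 1.242866e+00 2.752410e-01 5.180475e+00
9.50e+01 3.113043e+00 1.228032e+00 2.483700e-01 4.589444e+00
1.00e+02 2.668266e+00 1.213691e+00 2.253066e-01 4.107264e+00
1.10e+02 2.004056e+00 1.186395e+00 1.879870e-01 3.378438e+00
1.20e+02 1.543176e+00 1.160793e+00 1.593418e-01 2.863310e+00
1.30e+02 1.213418e+00 1.136725e+00 1.368616e-01 2.487005e+00
1.40e+02 9.712852e-01 1.114051e+00 1.188860e-01 2.204223e+00
1.50e+02 7.895051e-01 1.092647e+00 1.042799e-01 1.986432e+00
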