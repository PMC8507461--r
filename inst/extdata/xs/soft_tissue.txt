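# Linear photon attenuation coefficients for soft_tissue (1/cm), density 1.04 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.00e+01 5.129959e+00 2.226736e-01 1.895275e-01 5.542160e+00
1.25e+01 2.543235e+00 2.206491e-01 1.240347e-01 2.887919e+00
1.50e+01 1.433527e+00 2.186726e-01 8.772003e-02 1.739920e+00
1.75e+01 8.797566e-01 2.167424e-01 6.544853e-02 1.161948e+00
2.00e+01 5.763445e-01 2.148568e-01 5.078263e-02 8.419840e-01
2.50e+01 2.840979e-01 2.112138e-01 3.323427e-02 5.285459e-01
3.00e+01 1.593880e-01 2.077320e-01 2.350400e-02 3.906240e-01
3.50e+01 9.792496e-02 2.044010e-01 1.753650e-02 3.198624e-01
4.00e+01 6.421401e-02 2.012111e-01 1.360687e-02 2.790320e-01
4.50e+01 4.435054e-02 1.981536e-01 1.087848e-02 2.533826e-01
5.00e+01 3.185080e-02 1.952203e-01 8.904902e-03 2.359760e-01
5.50e+01 2.373192e-02 1.924037e-01 7.429901e-03 2.235655e-01
6.00e+01 1.814146e-02 1.896968e-01 6.297741e-03 2.141360e-01
6.50e+01 1.421818e-02 1.870933e-01 5.409247e-03 2.067207e-01
7.00e+01 1.134652e-02 1.845872e-01 4.698788e-03 2.006325e-01
7.50e+01 9.196958e-03 1.821730e-01 4.121504e-03 1.954915e-01
8.00e+01 7.556400e-03 1.798457e-01 3.645870e-03 1.910480e-01
8.50e+01 6.281245e-03 1.776005e-01 3.249198e-03 1.871310e-01
9.00e+01 5.276743e-03 1.754330e-01 2.914818e-03 1.836246e-01
9.50e+01 4.474855e-03 1.733391e-01 2.630252e-03 1.804442e-01
1.00e+02 3.827056e-03 1.713149e-01 2.386009e-03 1.775280e-01
1.10e+02 2.906042e-03 1.674619e-01 1.990793e-03 1.723588e-01
1.20e+02 2.260214e-03 1.638482e-01 1.687438e-03 1.677958e-01
1.30e+02 1.793656e-03 1.604510e-01 1.449372e-03 1.636940e-01
1.40e+02 1.448017e-03 1.572506e-01 1.259009e-03 1.599576e-01
1.50e+02 1.186383e-03 1.542293e-01 1.104330e-03 1.565200e-01
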