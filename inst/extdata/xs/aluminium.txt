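# Linear photon attenuation coefficients for aluminium (1/cm), density 2.699 g/cm3.
# Partials: photoelectric, incoherent (free-electron Klein-Nishina), coherent
# (Z_eff power-law model); totals anchored on standard 10-150 keV mass
# attenuation tabulations; mu_total = mu_pe + mu_compton + mu_rayleigh exactly.
# Columns: E_keV mu_pe mu_compton mu_rayleigh mu_total
1.00e+01 6.905396e+01 5.016483e-01 1.239161e+00 7.079477e+01
1.25e+01 3.530229e+01 4.970875e-01 8.109586e-01 3.661034e+01
1.50e+01 2.040438e+01 4.926347e-01 5.735276e-01 2.147055e+01
1.75e+01 1.273950e+01 4.882862e-01 4.279129e-01 1.365570e+01
2.00e+01 8.471196e+00 4.840383e-01 3.320249e-01 9.287259e+00
2.50e+01 4.253694e+00 4.758311e-01 2.172910e-01 4.946816e+00
3.00e+01 2.422812e+00 4.679871e-01 1.536729e-01 3.044472e+00
3.50e+01 1.501572e+00 4.604829e-01 1.146564e-01 2.076711e+00
4.00e+01 9.921209e-01 4.532967e-01 8.896388e-02 1.534381e+00
4.50e+01 6.877046e-01 4.464086e-01 7.112527e-02 1.205238e+00
5.00e+01 4.954799e-01 4.398003e-01 5.822167e-02 9.935019e-01
5.50e+01 3.685208e-01 4.334549e-01 4.857788e-02 8.505536e-01
6.00e+01 2.812498e-01 4.273568e-01 4.117564e-02 7.497822e-01
6.50e+01 2.196425e-01 4.214915e-01 3.536652e-02 6.765005e-01
7.00e+01 1.747036e-01 4.158456e-01 3.072143e-02 6.212707e-01
7.50e+01 1.411722e-01 4.104069e-01 2.694705e-02 5.785262e-01
8.00e+01 1.156571e-01 4.051639e-01 2.383728e-02 5.446582e-01
8.50e+01 9.604501e-02 4.001058e-01 2.124378e-02 5.173945e-01
9.00e+01 8.061045e-02 3.952227e-01 1.905754e-02 4.948907e-01
9.50e+01 6.830029e-02 3.905054e-01 1.719701e-02 4.760027e-01
1.00e+02 5.836415e-02 3.859453e-01 1.560011e-02 4.599096e-01
1.10e+02 4.382285e-02 3.772651e-01 1.301612e-02 4.341041e-01
1.20e+02 3.373577e-02 3.691239e-01 1.103274e-02 4.138924e-01
1.30e+02 2.652038e-02 3.614706e-01 9.476224e-03 3.974672e-01
1.40e+02 2.122353e-02 3.542605e-01 8.231603e-03 3.837157e-01
1.50e+02 1.724782e-02 3.474541e-01 7.220284e-03 3.719222e-01
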