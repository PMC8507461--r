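# Mass energy-absorption coefficient of dry air (cm^2/g),
# standard 10-150 keV tabulation; log-log interpolate between nodes.
# Columns: E_keV muen_over_rho_cm2_g
10 4.74200
15 1.33400
20 0.53890
30 0.15370
40 0.06833
50 0.04098
60 0.03041
80 0.02407
100 0.02325
150 0.02496
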