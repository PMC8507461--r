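# Hp(10) per unit photon fluence on the ICRU slab, normal incidence,
# pSv cm^2 (ICRP 74-style coefficients); log-log interpolate between nodes.
# Columns: E_keV hp10_per_fluence_pSv_cm2
10 0.061
15 0.830
20 1.050
30 0.810
40 0.640
50 0.550
60 0.510
80 0.530
100 0.610
150 0.890
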