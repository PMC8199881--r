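Vmax1_base_ref: 0.00846
Vmax1_base_low: 0.0007
ASCT_Vmax1: 2.53
CD4CD8_exp: -0.385
KM1: 1.13
kp1: 0.0005
kp2: 0.007
kp3: 0.007
k12: 0.14
k23: 0.191
k34: 0.355
ke1: 0.0104
ke2: 0.0104
ke3: 0.0104
ke4: 0.518
Vmax5_1: 2.57
Vmax5_2: 4.04
Vmax5_3: 3.78
Vmax5_4: 4.24
KM5: 276.0
K0: 5000.0
k5: 0.0023
MIXP: 0.803
expansion_denominator: tcell
omega2_Vmax1: 1.178654996342
omega2_Vmax5_2: 2.344197175313
sigma2_TN: 0.29957185798
sigma2_TCM: 0.552666554994
sigma2_TEM: 0.891998039305
sigma2_TEFF: 0.404421897486
sigma2_CD19: 0.842644191706
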