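! aug-cc-pVTZ (reconstruction).
! Primitive exponents: standard correlation-consistent tabulations.
! Contraction coefficients: re-derived from a spherically averaged
! fractional-occupation atomic SCF in the uncontracted primitive basis
! (the construction principle of the original general contractions).
****
H     0
S   3   1.00
              33.8700000      0.029186455
               5.0950000      0.217920329
               1.1590000      0.975530051
S   1   1.00
               0.3258000      1.000000000
S   1   1.00
               0.1027000      1.000000000
P   1   1.00
               1.4070000      1.000000000
P   1   1.00
               0.3880000      1.000000000
D   1   1.00
               1.0570000      1.000000000
S   1   1.00
               0.0252600      1.000000000
P   1   1.00
               0.1020000      1.000000000
D   1   1.00
               0.2470000      1.000000000
****
F     0
S   8   1.00
           19500.0000000      0.000832171
            2923.0000000      0.006436095
             664.5000000      0.033141071
             187.5000000      0.129635336
              60.6200000      0.378071558
              21.4200000      0.710370846
               7.9500000      0.574042867
               2.2570000      0.070456923
S   8   1.00
           19500.0000000      0.000401332
            2923.0000000      0.003119238
             664.5000000      0.016138243
             187.5000000      0.065299236
              60.6200000      0.204119003
              21.4200000      0.479402764
               7.9500000      0.605649353
               2.2570000     -0.597631124
S   1   1.00
               0.8815000      1.000000000
S   1   1.00
               0.3041000      1.000000000
P   3   1.00
              43.8800000      0.049860738
               9.9260000      0.311711376
               2.9300000      0.948867707
P   1   1.00
               0.9132000      1.000000000
P   1   1.00
               0.2672000      1.000000000
D   1   1.00
               3.1070000      1.000000000
D   1   1.00
               0.8550000      1.000000000
F   1   1.00
               1.9170000      1.000000000
S   1   1.00
               0.0915800      1.000000000
P   1   1.00
               0.0736100      1.000000000
D   1   1.00
               0.2920000      1.000000000
F   1   1.00
               0.7240000      1.000000000
****
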