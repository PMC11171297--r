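! cc-pVDZ (reconstruction).
! Primitive exponents: standard correlation-consistent tabulations.
! Contraction coefficients: re-derived from a spherically averaged
! fractional-occupation atomic SCF in the uncontracted primitive basis
! (the construction principle of the original general contractions).
****
H     0
S   3   1.00
              13.0100000      0.039524478
               1.9620000      0.277036206
               0.4446000      0.960046226
S   1   1.00
               0.1220000      1.000000000
P   1   1.00
               0.7270000      1.000000000
****
He     0
S   3   1.00
              38.3600000      0.048057393
               5.7700000      0.312643214
               1.2400000      0.948654156
S   1   1.00
               0.2976000      1.000000000
P   1   1.00
               1.2750000      1.000000000
****
Li     0
S   8   1.00
            1469.0000000      0.001252665
             220.5000000      0.009639115
              50.2600000      0.048537437
              14.2400000      0.178641697
               4.5810000      0.462621665
               1.5800000      0.741377853
               0.5640000      0.449169599
               0.0734500      0.014950767
S   8   1.00
            1469.0000000     -0.000307014
             220.5000000     -0.002394914
              50.2600000     -0.011950652
              14.2400000     -0.046202031
               4.5810000     -0.122972107
               1.5800000     -0.255775744
               0.5640000     -0.324656595
               0.0734500      0.900983601
S   1   1.00
               0.0280500      1.000000000
P   1   1.00
               1.5340000      1.000000000
P   1   1.00
               0.2749000      1.000000000
P   1   1.00
               0.0736200      1.000000000
D   1   1.00
               0.1144000      1.000000000
****
C     0
S   8   1.00
            6665.0000000      0.001116340
            1000.0000000      0.008427548
             228.0000000      0.044099969
              64.7100000      0.158558158
              21.0600000      0.463373544
               6.8820000      0.785857698
               2.4820000      0.374636089
               0.5329000      0.014236277
S   8   1.00
            6665.0000000     -0.000252986
            1000.0000000     -0.001962819
             228.0000000     -0.010006104
              64.7100000     -0.039121977
              21.0600000     -0.116327691
               6.8820000     -0.291761830
               2.4820000     -0.182756057
               0.5329000      0.930756982
S   1   1.00
               0.1687000      1.000000000
P   3   1.00
               9.4390000      0.072807148
               2.0020000      0.411045225
               0.5456000      0.908702890
P   1   1.00
               0.1517000      1.000000000
D   1   1.00
               0.5500000      1.000000000
****
N     0
S   8   1.00
            9046.0000000      0.001153447
            1357.0000000      0.008885351
             309.3000000      0.045175619
              87.7300000      0.170174276
              28.5600000      0.459405865
              10.2100000      0.740287303
               3.8380000      0.457442347
               0.7466000      0.024229299
S   8   1.00
            9046.0000000     -0.000251821
            1357.0000000     -0.001995835
             309.3000000     -0.009870943
              87.7300000     -0.040596140
              28.5600000     -0.111018920
              10.2100000     -0.263140098
               3.8380000     -0.198231480
               0.7466000      0.936689297
S   1   1.00
               0.2248000      1.000000000
P   3   1.00
              13.5500000      0.074871247
               2.9170000      0.413907184
               0.7973000      0.907234887
P   1   1.00
               0.2185000      1.000000000
D   1   1.00
               0.8170000      1.000000000
****
O     0
S   8   1.00
           11720.0000000      0.001172801
            1759.0000000      0.009031595
             400.8000000      0.045953593
             113.7000000      0.173033874
              37.0300000      0.467265694
              13.2700000      0.741309618
               5.0250000      0.446511880
               1.0130000      0.024790404
S   8   1.00
           11720.0000000     -0.000262452
            1759.0000000     -0.002078665
             400.8000000     -0.010299533
             113.7000000     -0.042355586
              37.0300000     -0.116509191
              13.2700000     -0.273456331
               5.0250000     -0.190663810
               1.0130000      0.934553417
S   1   1.00
               0.3023000      1.000000000
P   3   1.00
              17.7000000      0.077910918
               3.8540000      0.417046518
               1.0460000      0.905539668
P   1   1.00
               0.2753000      1.000000000
D   1   1.00
               1.1850000      1.000000000
****
F     0
S   8   1.00
           14710.0000000      0.001191650
            2207.0000000      0.009179004
             502.8000000      0.046721261
             142.6000000      0.175948303
              46.4700000      0.474053639
              16.7000000      0.741786930
               6.3560000      0.437233440
               1.3160000      0.025017218
S   8   1.00
           14710.0000000     -0.000271623
            2207.0000000     -0.002150874
             502.8000000     -0.010673146
             142.6000000     -0.043900185
              46.4700000     -0.121075077
              16.7000000     -0.281352214
               6.3560000     -0.183853916
               1.3160000      0.932916745
S   1   1.00
               0.3897000      1.000000000
P   3   1.00
              22.6700000      0.080074152
               4.9770000      0.421447506
               1.3470000      0.903310650
P   1   1.00
               0.3471000      1.000000000
D   1   1.00
               1.6400000      1.000000000
****
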