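! STO-3G minimal basis, constructed from the standard three-Gaussian
! STO fits with per-element Slater zeta scaling (alpha * zeta^2).
****
H     0
S   3   1.00
           3.425250914      0.154328967
           0.623913729      0.535328142
           0.168855403      0.444634542
****
He     0
S   3   1.00
           6.362421394      0.154328967
           1.158922999      0.535328142
           0.313649790      0.444634542
****
Li     0
S   3   1.00
          16.119574752      0.154328967
           2.936200662      0.535328142
           0.794650484      0.444634542
S   3   1.00
           0.636290086     -0.099967229
           0.147860070      0.399512826
           0.048088614      0.700115469
P   3   1.00
           0.636290086      0.155916275
           0.147860070      0.607683719
           0.048088614      0.391957393
****
Be     0
S   3   1.00
          30.167870693      0.154328967
           5.495115303      0.535328142
           1.487192647      0.444634542
S   3   1.00
           1.314833811     -0.099967229
           0.305538974      0.399512826
           0.099370613      0.700115469
P   3   1.00
           1.314833811      0.155916275
           0.305538974      0.607683719
           0.099370613      0.391957393
****
B     0
S   3   1.00
          48.791113175      0.154328967
           8.887362167      0.535328142
           2.405267031      0.444634542
S   3   1.00
           2.236957335     -0.099967229
           0.519820560      0.399512826
           0.169061535      0.700115469
P   3   1.00
           2.236957335      0.155916275
           0.519820560      0.607683719
           0.169061535      0.391957393
****
C     0
S   3   1.00
          71.616837349      0.154328967
          13.045096317      0.535328142
           3.530512147      0.444634542
S   3   1.00
           2.941250924     -0.099967229
           0.683483175      0.399512826
           0.222289620      0.700115469
P   3   1.00
           2.941250924      0.155916275
           0.683483175      0.607683719
           0.222289620      0.391957393
****
N     0
S   3   1.00
          99.106168956      0.154328967
          18.052312382      0.535328142
           4.885660221      0.444634542
S   3   1.00
           3.780457896     -0.099967229
           0.878496746      0.399512826
           0.285713994      0.700115469
P   3   1.00
           3.780457896      0.155916275
           0.878496746      0.607683719
           0.285713994      0.391957393
****
O     0
S   3   1.00
         130.709321363      0.154328967
          23.808866041      0.535328142
           6.443608290      0.444634542
S   3   1.00
           5.033154004     -0.099967229
           1.169596260      0.399512826
           0.380388454      0.700115469
P   3   1.00
           5.033154004      0.155916275
           1.169596260      0.607683719
           0.380388454      0.391957393
****
F     0
S   3   1.00
         166.679134046      0.154328967
          30.360812320      0.535328142
           8.216820642      0.444634542
S   3   1.00
           6.464806698     -0.099967229
           1.502281418      0.399512826
           0.488587836      0.700115469
P   3   1.00
           6.464806698      0.155916275
           1.502281418      0.607683719
           0.488587836      0.391957393
****
Ne     0
S   3   1.00
         207.015607007      0.154328967
          37.708151219      0.535328142
          10.205297277      0.444634542
S   3   1.00
           8.246319520     -0.099967229
           1.916266512      0.399512826
           0.623228443      0.700115469
P   3   1.00
           8.246319520      0.155916275
           1.916266512      0.607683719
           0.623228443      0.391957393
****
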