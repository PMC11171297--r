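 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
  1.6585666964299426E+00    1    1    1    1
 -1.1170993419081200E-01    2    1    1    1
  1.3337569205114350E-02    2    1    2    1
  3.6670098120383771E-01    2    2    1    1
  6.2103015619516221E-03    2    2    2    1
  4.8731087788151195E-01    2    2    2    2
  1.3857454528329768E-01    3    1    1    1
 -1.1215759192514470E-02    3    1    2    1
  1.5868078089802926E-02    3    1    2    2
  2.1662222295351311E-02    3    1    3    1
 -1.3451215145997742E-02    3    2    1    1
  3.3493876380828614E-03    3    2    2    1
  4.8579610887927199E-02    3    2    2    2
  1.7628201468943445E-04    3    2    3    1
  1.3063984990134409E-02    3    2    3    2
  3.9563357250425568E-01    3    3    1    1
 -1.1035051501170987E-02    3    3    2    1
  2.2360998753593364E-01    3    3    2    2
 -1.8246220632079195E-03    3    3    3    1
 -7.4841482105558474E-03    3    3    3    2
  3.3788210186203516E-01    3    3    3    3
  9.8178841048112038E-03    4    1    4    1
  7.4884611171340083E-03    4    2    4    1
  2.3422663577043205E-02    4    2    4    2
 -1.0257697416280513E-02    4    3    4    1
 -1.9276883445536307E-02    4    3    4    2
  4.1276674024006456E-02    4    3    4    3
  3.9631932061656772E-01    4    4    1    1
 -4.3558028874550944E-03    4    4    2    1
  2.7017142672681804E-01    4    4    2    2
  4.9752912933876629E-03    4    4    3    1
 -5.7674807075894733E-03    4    4    3    2
  2.8199123732655673E-01    4    4    3    3
  3.1294541031477707E-01    4    4    4    4
  9.8178841048112038E-03    5    1    5    1
  7.4884611171340083E-03    5    2    5    1
  2.3422663577043205E-02    5    2    5    2
 -1.0257697416280513E-02    5    3    5    1
 -1.9276883445536307E-02    5    3    5    2
  4.1276674024006456E-02    5    3    5    3
  1.6869130913836485E-02    5    4    5    4
  3.9631932061656772E-01    5    5    1    1
 -4.3558028874550944E-03    5    5    2    1
  2.7017142672681804E-01    5    5    2    2
  4.9752912933876629E-03    5    5    3    1
 -5.7674807075894733E-03    5    5    3    2
  2.8199123732655673E-01    5    5    3    3
  2.7920714848710410E-01    5    5    4    4
  3.1294541031477707E-01    5    5    5    5
  5.3044933731902222E-02    6    1    1    1
 -8.9066631160501907E-03    6    1    2    1
 -6.8375742275457417E-03    6    1    2    2
  2.3558928499379178E-03    6    1    3    1
 -1.6892833580946791E-03    6    1    3    2
  1.0443519286981269E-02    6    1    3    3
  5.9107782077193140E-04    6    1    4    4
  5.9107782077193140E-04    6    1    5    5
  8.5494991517509784E-03    6    1    6    1
 -4.1496804881869825E-02    6    2    1    1
  4.6926659449241289E-03    6    2    2    1
  1.2679501658454678E-01    6    2    2    2
 -5.5964196993899559E-04    6    2    3    1
  3.4600632025656296E-02    6    2    3    2
 -1.2415973865039703E-02    6    2    3    3
 -1.6292189906322131E-02    6    2    4    4
 -1.6292189906322131E-02    6    2    5    5
  1.1914763471524750E-04    6    2    6    1
  1.2392643349703732E-01    6    2    6    2
 -1.7665887616411940E-02    6    3    1    1
  3.6667935409925067E-03    6    3    2    1
  5.1366892521705169E-02    6    3    2    2
  4.3956269974006939E-03    6    3    3    1
  9.4086147238151528E-03    6    3    3    2
 -3.5979641639265578E-02    6    3    3    3
 -2.2381188521842545E-03    6    3    4    4
 -2.2381188521842545E-03    6    3    5    5
 -4.3058586838445210E-03    6    3    6    1
  3.1903648766733322E-02    6    3    6    2
  2.6448191831513233E-02    6    3    6    3
 -6.1123203277197152E-03    6    4    4    1
 -1.9574458775984092E-02    6    4    4    2
  1.3722953342747824E-02    6    4    4    3
  1.9722236696666909E-02    6    4    6    4
 -1.1371229279459851E-16    6    5    1    1
 -6.1123203277197152E-03    6    5    5    1
 -1.9574458775984092E-02    6    5    5    2
  1.3722953342747824E-02    6    5    5    3
  1.9722236696666909E-02    6    5    6    5
  3.6173095223796892E-01    6    6    1    1
  3.2715951951903383E-03    6    6    2    1
  4.5384432140902448E-01    6    6    2    2
  1.1336329566416498E-02    6    6    3    1
  4.3353479394185331E-02    6    6    3    2
  2.4143556829172283E-01    6    6    3    3
  2.6812832419505761E-01    6    6    4    4
  2.6812832419505761E-01    6    6    5    5
 -3.0683841380602624E-03    6    6    6    1
  1.3420544426230599E-01    6    6    6    2
  4.4076925695128513E-02    6    6    6    3
  4.5378708516554456E-01    6    6    6    6
 -4.7273931303699168E+00    1    1    0    0
  1.0549963268422298E-01    2    1    0    0
 -1.4926460838976889E+00    2    2    0    0
 -1.6696131387236973E-01    3    1    0    0
 -3.2892938131135398E-02    3    2    0    0
 -1.1255444947820836E+00    3    3    0    0
 -1.1357997239172284E+00    4    4    0    0
  2.7004397723712351E-16    5    2    0    0
 -1.1357997239172284E+00    5    5    0    0
 -3.4677119274255958E-02    6    1    0    0
 -5.2708070402946908E-02    6    2    0    0
 -3.0445485308447415E-02    6    3    0    0
  3.7775328000737178E-16    6    5    0    0
 -9.5096646042668531E-01    6    6    0    0
  9.9220727047500001E-01    0    0    0    0
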