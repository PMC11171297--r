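 &FCI NORB=4,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,
  ISYM=1,
 &END
  5.0949548578529869E-01    1    1    1    1
 -2.0200525568529022E-15    2    1    1    1
  1.5718483850958229E-01    2    1    2    1
  4.4641663873520449E-01    2    2    1    1
  6.1664871867135570E-16    2    2    2    1
  4.6417507703499833E-01    2    2    2    2
  8.3557308229635127E-02    3    1    1    1
  6.6972858780473263E-16    3    1    2    1
 -8.6746940432227172E-03    3    1    2    2
  1.0754242142951236E-01    3    1    3    1
  1.0305678236243020E-15    3    2    1    1
 -9.9540661939279795E-02    3    2    2    1
 -9.8690344213256209E-16    3    2    2    2
 -5.8258923720704438E-16    3    2    3    1
  1.3730716306505764E-01    3    2    3    2
  4.5767259547132644E-01    3    3    1    1
 -1.2431229421376007E-15    3    3    2    1
  4.5786216488461234E-01    3    3    2    2
  9.8920190303863516E-03    3    3    3    1
  5.7839658758019463E-16    3    3    3    2
  4.7877988008424438E-01    3    3    3    3
  9.2263377075559255E-16    4    1    1    1
 -4.4007697940055615E-02    4    1    2    1
  6.2507180782197248E-16    4    1    3    1
 -5.0104766914699735E-02    4    1    3    2
  1.1377242134678754E-16    4    1    3    3
  9.6102233029679851E-02    4    1    4    1
 -8.6370515376788151E-02    4    2    1    1
 -6.3069291509205896E-03    4    2    2    2
 -9.7238681450405512E-02    4    2    3    1
 -6.9557764220838601E-16    4    2    3    2
 -5.5842711333063243E-03    4    2    3    3
  1.0367958290078302E-01    4    2    4    2
  1.3691153974773687E-15    4    3    1    1
 -1.4947436887593146E-01    4    3    2    1
 -1.2780939565086554E-15    4    3    2    2
 -5.1494029427602753E-16    4    3    3    1
  1.0037113792591967E-01    4    3    3    2
  5.5617835401809408E-16    4    3    3    3
  4.1739333368567520E-02    4    3    4    1
 -2.2605052555825975E-16    4    3    4    2
  1.6149070886713773E-01    4    3    4    3
  5.3693667977120041E-01    4    4    1    1
  4.7627288288387465E-01    4    4    2    2
  8.8383095500622844E-02    4    4    3    1
  4.9410460197714651E-01    4    4    3    3
  1.2732851962357104E-16    4    4    4    1
 -9.6532756066496708E-02    4    4    4    2
 -7.7017708319309049E-16    4    4    4    3
  5.9951975957373038E-01    4    4    4    4
 -1.8951280489695035E+00    1    1    0    0
  1.3493564196524608E-15    2    1    0    0
 -1.5912987076032341E+00    2    2    0    0
 -1.6574858367957368E-01    3    1    0    0
 -6.7328987345919527E-16    3    2    0    0
 -1.2617952645404857E+00    3    3    0    0
 -5.1055122644351020E-16    4    1    0    0
  1.3504026017514809E-01    4    2    0    0
  1.0818058654694058E-15    4    3    0    0
 -8.7272153823122800E-01    4    4    0    0
  2.4137907866526311E+00    0    0    0    0
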