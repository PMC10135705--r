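cohort,chi_square
1,2.6787782385484697e+00
2,1.9616514566970725e-01
3,6.6402188678014735e-04
4,6.1619290700748663e-01
5,1.0285856988705095e+00
6,2.8295254451880645e+00
7,1.0320884695375980e+00
8,8.2129661092160788e-01
9,1.6225260062347762e+00
10,1.7912635560679530e-01
11,7.3954169339189662e+00
12,1.0198568378047923e+00
13,4.5974023066169023e-01
14,1.1696856841263108e+01
15,2.7215442463125283e-01
16,1.5874132095064281e+01
17,8.4699893509574797e-02
18,2.9847532555634375e+00
19,5.1703466160185183e+00
20,1.6126387512403593e+01
21,1.6302265326151966e-01
22,2.1213621017996642e+00
23,1.0654314748778090e+01
24,5.1787664592677967e+00
25,5.3549782453533910e+00
26,5.6037894004161912e-02
27,8.2785127166912265e+00
28,1.7565394315468887e+00
29,1.9488538556743670e-01
30,5.7905430445703399e+00
31,6.9997294964999979e-01
32,2.7752579404078905e+00
33,3.5457519028944215e+00
34,4.7227278388325544e+00
35,3.9802146877732292e+00
36,3.3451962378335220e-01
37,1.5750571832911894e-02
38,1.5003968882481636e-01
39,5.6624926088987027e-01
40,2.4599550480018773e-01
41,6.7987932899513237e-01
42,1.8875193122652015e-01
43,8.9648627597132862e+00
44,7.2159155238389805e-01
45,4.5628560687677497e-02
46,3.8585666202824593e+00
47,3.6495742975571827e-01
48,7.3619291870702188e+00
49,6.2939909740471904e+00
50,2.7137646538422722e-01
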