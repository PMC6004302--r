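interval_cm,c14_age_bp,c14_err,f14c,f14c_err
0.5,405,20,0.9508,0.0024
1,591,19,0.9290,0.0022
1.5,513,19,0.9382,0.0023
2,536,20,0.9354,0.0023
2.5,657,20,0.9215,0.0022
3,,,,
3.5,853,20,0.8993,0.0022
4,1044,21,0.8781,0.0022
4.5,1005,20,0.8824,0.0022
5,661,19,0.9211,0.0021
5.5,349,18,0.9574,0.0022
6,614,19,0.9264,0.0022
6.5,788,21,0.9065,0.0023
7,373,19,0.9546,0.0022
7.5,1070,18,0.8753,0.0020
8,865,21,0.8979,0.0024
8.5,519,19,0.9375,0.0022
9,635,19,0.9240,0.0022
9.5,955,21,0.8879,0.0023
10,749,19,0.9110,0.0021
10.5,945,19,0.8891,0.0021
11,1012,23,0.8816,0.0025
11.5,872,22,0.8971,0.0025
12,1056,19,0.8768,0.0021
12.5,846,20,0.9001,0.0023
13,736,25,0.9125,0.0028
13.5,866,19,0.8978,0.0021
14,1123,64,0.8695,0.0069
14.5,1049,45,0.8776,0.0049
15,1233,20,0.8578,0.0021
19.5-20.5,7230,128,,
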