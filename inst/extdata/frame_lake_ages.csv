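depth,sed_rate_pb210,age_pb210,sed_rate_ash
0,1.5,2012.00,0.34
1,0.48,2011.33,0.34
2,0.71,2009.23,0.34
2.5,0.99,2008.53,0.34
3,1.13,2008.02,0.34
3.5,1.18,2007.58,0.34
4,0.75,2007.16,0.34
4.5,0.52,2006.48,0.34
5,0.20,2005.52,0.34
6,0.43,2000.47,0.34
7,0.43,1998.12,0.34
8,0.45,1995.81,0.34
9,0.60,1993.60,0.34
10,0.45,1991.94,0.34
11,0.36,1989.70,0.34
12,0.24,1986.96,0.34
13,0.24,1982.74,0.34
14,0.24,1978.64,0.34
15,0.17,1974.47,0.34
16,0.17,1968.58,0.34
17,0.17,1962.69,0.34
18,0.17,1956.81,0.34
19,0.17,1950.92,0.34
20,0.72,,0.34
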