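sample,sdi,dc_ratio
FL1,2.41,0.70
FL2,2.14,0.70
FL3,2.47,0.55
FL4,2.49,0.69
FL5,2.65,0.66
FL6,2.36,0.63
FL7,2.09,0.20
FL8,2.38,0.21
FL9,2.37,0.26
FL10,2.20,0.30
FL11,2.47,0.33
FL12,2.27,0.32
FL13,2.06,0.28
FL14,2.41,0.45
FL15,2.45,0.40
FL16,2.60,0.54
FL17,2.61,0.62
FL18,2.59,0.68
FL19,2.45,0.57
FL20,2.38,0.66
FL21,2.48,0.80
FL22,2.36,0.85
FL23,2.26,0.89
FL24,2.39,0.90
FL25,2.19,0.92
FL26,2.37,0.86
FL27,2.42,0.77
FL28,2.57,0.75
FL29,2.35,0.80
FL30,2.27,0.82
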