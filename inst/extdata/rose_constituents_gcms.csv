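constituent,formula,g10,g9,g8,g7,g6,g5,g4,g3,g2,g1
Phenyl ethyl alcohol,C_8_H_10_O,0.64,0.18,0.61,0.37,0.3,0.3,0.21,-,-,-
Trans rose oxide,C_10_H_18_O,1.25,0.61,0.5,0.61,0.4,0.23,0.12,0.32,0.18,0.4
Citronellol,C_10_H_20_O,28.18,53.1,33.7,24.1,13.35,8.48,2.14,4.73,0.48,1.25
Nerol,C_10_H_18_O,16.2,2.01,3.56,0.1,0.1,0.6,-,-,-,-
Geraniol,C_10_H_18_O,30.02,15.16,26.05,12.1,7.25,6.15,6.33,2.66,3.25,0.5
Geranial,C_10_H_16_O,0.48,0.26,0.27,0.1,0.21,0.2,0.1,0.14,0.15,-
α-Eudesmol,C_15_H_26_O,0.72,-,0.61,-,3.15,2.18,-,2.35,2.86,1.73
β-Eudesmol,C_15_H_26_O,-,-,0.67,-,2.84,2.52,2.01,2.77,4.33,1.9
γ-Eudesmol,C_15_H_26_O,-,-,0.57,-,2.68,2.43,-,1.4,1.77,1.48
Cyclohexanemethanol,C_15_H_26_O,-,-,-,-,1.25,0.53,-,0.17,0.62,0.44
Dioctyl Phthalate,C_24_H_38_O_4_,-,-,-,-,-,-,-,-,-,15.9
Farnesol,C_15_H_26_O,-,-,0.27,1.53,-,-,-,0.9,0.95,-
Octyl phthalate,C_24_H_38_O_4_,2.48,-,0.28,-,-,0.22,3.91,-,12.0,-
Geranyl acetate,C_12_H_20_O_2_,2.05,0.44,1.12,1.24,0.71,-,0.5,0.1,-,-
Methyleugenol,C_11_H_14_O_2_,-,0.28,0.25,0.75,-,-,-,0.15,-,-
Diisooctyl phthalate,C_24_H_38_O_4_,-,5.16,-,-,-,-,-,4.88,-,-
Linalool,C_10_H_18_O,-,-,0.53,0.31,-,-,0.83,-,-,-
Neral,C_10_H_16_O,1.3,1.0,0.94,0.9,0.78,0.7,0.66,0.34,0.23,0.1
3-Methyl-4-isopropylphenol,C_10_H_14_O,-,0.53,-,0.3,-,-,-,-,-,-
Eugenol,C_10_H_12_O_2_,-,-,-,0.4,-,-,-,-,-,-
Apilo,C_12_H_14_O_4_,-,-,0.23,0.42,-,-,-,-,-,-
Nonacosane,C_29_H_6_O,-,-,0.37,0.56,-,-,-,-,-,-
Nonanal,C_9_H_18_O,-,-,0.13,-,-,-,-,-,-,-
Anethole,C_10_H_12_O,-,0.55,0.5,-,-,-,-,-,-,-
Chavibetol,C_10_H_12_O_2_,-,0.22,0.28,-,-,-,-,-,-,-
Docosane,C_22_H_46_,-,3.82,4.0,0.53,4.05,4.83,6.51,5.0,0.55,-
Pentacosane,C_25_H_52_,-,2.25,-,2.06,1.65,-,-,-,2.44,-
z-5-Nonadecene,C_19_H_38_,-,2.93,-,-,-,6.35,6.33,6.35,5.35,5.6
Nonadecane,C_19_H_40_,10.94,12.76,14.2,17.6,35.9,40.3,37.2,33.7,30.5,33.1
Eicosane,C_20_H_42_,1.9,2.48,2.28,3.12,2.73,3.76,4.15,5.4,3.43,3.28
Hexadecane,C_20_H_42_,-,-,-,-,-,-,-,-,-,4.48
1-Tetradecene,C_14_H_28_,-,-,-,-,-,-,-,0.13,-,-
9-Eicosene,C_20_H_40_,-,-,0.2,-,-,-,-,0.18,-,-
9-Nonadecene,C_19_H_38_,-,0.21,0.33,-,-,-,0.35,0.37,-,-
cis-9-Tricosene,C_23_H_46_,-,0.46,-,0.55,-,-,-,0.28,-,-
Bicyclo[10.8.0]eicosane-cis,C_20_H_38_,-,-,-,-,-,-,-,-,-,0.13
Hexacosane,C_26_H_54_,-,-,-,-,-,0.2,-,0.2,-,-
Octacosane,C_28_H_58_,-,-,0.09,-,-,-,-,0.07,-,-
Heneicosane,C_21_H_44_,10.0,9.66,11.2,11.6,17.34,20.7,25.7,19.6,20.2,20.0
Tetracosane,C_24_H_50_,0.5,2.6,0.33,0.41,-,2.42,0.27,0.6,3.68,2.87
Neopentylidenecyclohexane,C_11_H_20_,-,-,-,-,-,1.35,-,-,-,-
"1,21-Docosadiene",C_22_H_42_,-,-,-,-,-,0.15,-,-,-,-
1-Octadecene,C_18_H_36_,-,-,-,-,6.03,-,-,-,-,-
8-Heptadecan,C_17_H_34_,-,-,0.35,-,1.5,1.84,-,1.16,0.86,0.52
"2,6-Octadiene, 2,6-dimethyl",C_10_H_18_,-,0.36,0.37,0.35,-,-,-,-,-,-
Heptacosane,C_27_H_56_,-,0.24,2.4,2.13,2.0,0.07,3.37,2.66,-,2.91
Bergamoten,C_15_H_24_,-,-,-,0.84,-,-,-,-,-,-
Teriacontane,C_30_H_62_,1.78,0.4,-,-,-,-,-,-,-,0.31
1-Nonadecane,C_19_H_38_,-,-,-,3.5,-,-,-,-,-,-
Tricosane,C_23_H_48_,-,-,-,3.75,-,-,-,-,-,-
"1,19-Eicosadiene",C_20_H_38_,-,-,0.16,-,-,-,-,-,-,-
"5-Eicosene, (E)",C_20_H_40_,3.96,-,-,-,-,-,-,-,-,-
Pentadecane,C_15_H_32_,-,0.21,0.21,-,0.28,-,-,0.4,-,0.36
Heptadecane,C_17_H_36_,-,1.6,1.78,1.56,2.1,3.67,2.51,3,2.17,2.93
7-Tetradecyne,C_14_H_26_,-,-,-,-,-,-,-,-,-,0.4
Octadecane,C_18_H_38_,-,0.6,2.16,0.4,-,0.4,2.68,0.27,5.0,0.25
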