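analyte,group,mean,sd,lower,upper
IL-10,BI-ALCL,2601.06,2284.90,58.36,6950
IL-10,RS-All,3.82,4.53,0.35,19.69
IL-10,RS-A,3.34,2.81,1.46,8.40
IL-10,RS-C,4.04,2.72,0.48,7.86
IL-10,RS-M,4.01,7.71,0.35,19.69
IL-10,T-LCL,1136.43,2582.54,0.38,6950
IL-6,BI-ALCL,7965.87,12041.76,159.81,42900
IL-6,RS-All,5732.29,10539.82,6.12,42900
IL-6,RS-A,7141.83,7699.36,1353.45,19149.33
IL-6,RS-C,3378.96,5746.51,6.12,16904.51
IL-6,RS-M,7460.54,17372.17,7.42,42900
IL-6,T-LCL,14052.88,19822.55,4.19,42900
IL-13,BI-ALCL,1403.69,1367.37,68.64,4950.67
IL-13,RS-All,12.97,16.62,0.83,67.45
IL-13,RS-A,5.72,6.51,0.83,17.86
IL-13,RS-C,23.52,21.83,3.37,67.45
IL-13,RS-M,6.14,6.56,3.37,19.53
IL-13,T-LCL,5488.42,6166.29,1.31,13800.00
Eotaxin,BI-ALCL,668.49,154.72,424.98,954.65
Eotaxin,RS-All,179.54,216.96,0.31,671.47
Eotaxin,RS-A,184.72,239.00,20.69,654.35
Eotaxin,RS-C,238.58,252.77,17.90,671.47
Eotaxin,RS-M,95.65,135.08,0.31,358.65
Eotaxin,T-LCL,5.73,6.55,1.36,19.64
IL-10/IL-6,BI-ALCL,3.04,6.04,0.01,20.43
IL-10/IL-6,RS-All,0.02,0.03,0,0.10
IL-10/IL-6,RS-A,0.001,0.002,0,0.01
IL-10/IL-6,RS-C,0.03,0.04,0,0.09
IL-10/IL-6,RS-M,0.03,0.04,0.001,0.10
IL-10/IL-6,T-LCL,3.29,8.14,0,21.73
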