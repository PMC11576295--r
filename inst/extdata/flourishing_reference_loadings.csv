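item_id,instrument,facet,lambda_general,lambda_specific,cd_published
MHC-SF-EWB-1,MHC-SF,EWB,0.677,0.700,0.072
MHC-SF-EWB-2,MHC-SF,EWB,0.717,0.760,0.123
MHC-SF-EWB-3,MHC-SF,EWB,0.790,0.824,0.087
MHC-SF-SWB-1,MHC-SF,SWB,0.575,0.600,0.091
MHC-SF-SWB-2,MHC-SF,SWB,0.520,0.558,0.148
MHC-SF-SWB-3,MHC-SF,SWB,0.474,0.520,0.203
MHC-SF-SWB-4,MHC-SF,SWB,0.450,0.502,0.243
MHC-SF-SWB-5,MHC-SF,SWB,0.460,0.509,0.223
MHC-SF-PWB-1,MHC-SF,PWB,0.710,0.744,0.099
MHC-SF-PWB-2,MHC-SF,PWB,0.692,0.718,0.077
MHC-SF-PWB-3,MHC-SF,PWB,0.658,0.689,0.097
MHC-SF-PWB-4,MHC-SF,PWB,0.567,0.602,0.128
MHC-SF-PWB-5,MHC-SF,PWB,0.584,0.613,0.098
MHC-SF-PWB-6,MHC-SF,PWB,0.811,0.820,0.023
PERMA-A-1,PERMA,A,0.800,0.811,0.028
PERMA-A-2,PERMA,A,0.676,0.688,0.038
PERMA-A-3,PERMA,A,0.592,0.601,0.031
PERMA-E-1,PERMA,E,0.429,0.440,0.054
PERMA-E-2,PERMA,E,0.579,0.587,0.030
PERMA-E-3,PERMA,E,0.260,0.274,0.111
PERMA-P-1,PERMA,P,0.818,0.833,0.038
PERMA-P-2,PERMA,P,0.819,0.833,0.034
PERMA-P-3,PERMA,P,0.861,0.871,0.021
PERMA-M-1,PERMA,M,0.841,0.850,0.022
PERMA-M-2,PERMA,M,0.791,0.799,0.020
PERMA-M-3,PERMA,M,0.785,0.801,0.041
PERMA-R-1,PERMA,R,0.579,0.591,0.041
PERMA-R-2,PERMA,R,0.655,0.665,0.032
PERMA-R-3,PERMA,R,0.668,0.683,0.045
FS-1,FS,FS,0.757,0.790,0.090
FS-2,FS,FS,0.548,0.599,0.195
FS-3,FS,FS,0.699,0.757,0.173
FS-4,FS,FS,0.520,0.623,0.438
FS-5,FS,FS,0.576,0.682,0.402
FS-6,FS,FS,0.694,0.780,0.266
FS-7,FS,FS,0.727,0.758,0.086
FS-8,FS,FS,0.561,0.638,0.294
WBCF-PC-1,WBCF,PC,0.691,0.688,0.007
WBCF-PC-2,WBCF,PC,0.173,0.170,0.001
WBCF-PC-3,WBCF,PC,0.679,0.678,0.000
WBCF-PC-4,WBCF,PC,0.473,0.475,0.000
WBCF-PC-5,WBCF,PC,0.570,0.570,0.007
WBCF-PC-6,WBCF,PC,0.810,0.813,0.000
WBCF-PF-1,WBCF,PF,0.690,0.688,0.000
WBCF-PF-2,WBCF,PF,0.351,0.351,0.000
WBCF-PF-3,WBCF,PF,0.646,0.643,0.000
WBCF-PF-4,WBCF,PF,0.572,0.571,0.000
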