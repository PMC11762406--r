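gene,uniprot_id,period,acrophase_dlmo_h,p_value,amplitude_z
AZGP1,P25311,12,4.4,0.009,0.28
ITIH2,P19823,12,10.0,0.019,0.30
FGA,P02671,12,7.9,0.019,0.30
KNG1,P01042,12,5.0,0.020,0.23
APOA2,P02652,12,10.1,0.021,0.27
IGK,P0DOX7,12,3.7,0.039,0.27
PLG,P00747,12,5.8,0.039,0.22
IGHM,P01871,12,0.3,0.042,0.31
IGKC,P01834,12,3.5,0.049,0.27
PLG,P00747,24,-0.9,0.010,0.37
APOC3,P02656,24,7.5,0.011,0.41
FGA,P02671,24,-2.1,0.025,0.32
FGB,P02675,24,0.0,0.034,0.31
CFH,P08603,24,0.2,0.042,0.29
APOE,P02649,24,5.4,0.043,0.37
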