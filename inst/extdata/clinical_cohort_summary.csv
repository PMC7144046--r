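group,variable,preop,postop,preop_logmar,postop_logmar
ANN,udva_decimal,0.17,0.37,0.77,0.43
ANN,cdva_decimal,0.60,0.73,0.22,0.14
ANN,se_d,-3.89,-2.58,,
ANN,simk1_d,45.58,43.71,,
ANN,simk2_d,49.80,47.13,,
ANN,simk_avg_d,47.56,45.33,,
ANN,total_rms_um,5.36,4.91,,
ANN,hoa_rms_um,3.69,3.34,,
ANN,astigmatism_rms_um,3.62,3.47,,
ANN,coma_like_rms_um,3.56,2.71,,
ANN,spherical_like_rms_um,0.93,1.84,,
nomogram,udva_decimal,0.12,0.36,0.92,0.44
nomogram,cdva_decimal,0.54,0.62,0.27,0.21
nomogram,se_d,-4.96,-1.80,,
nomogram,simk1_d,44.37,43.15,,
nomogram,simk2_d,48.95,45.98,,
nomogram,simk_avg_d,46.50,44.98,,
nomogram,total_rms_um,5.66,4.39,,
nomogram,hoa_rms_um,3.30,3.42,,
nomogram,astigmatism_rms_um,4.16,2.36,,
nomogram,coma_like_rms_um,3.10,2.93,,
nomogram,spherical_like_rms_um,1.05,1.58,,
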