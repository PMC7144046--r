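decimal,logmar,context
0.90,0.05,grading threshold grade I
0.60,0.22,grading threshold grade II
0.40,0.40,grading threshold grade III
0.20,0.70,grading threshold grade IV
0.73,0.14,ANN cohort postoperative CDVA mean
0.60,0.22,ANN cohort preoperative CDVA mean
0.17,0.77,ANN cohort preoperative UDVA mean
0.37,0.43,ANN cohort postoperative UDVA mean
0.12,0.92,nomogram cohort preoperative UDVA mean
0.36,0.44,nomogram cohort postoperative UDVA mean
0.54,0.27,nomogram cohort preoperative CDVA mean
0.62,0.21,nomogram cohort postoperative CDVA mean
0.22,0.66,ICRS-only subgroup preoperative UDVA mean
0.14,0.85,ICRS+CXL subgroup preoperative UDVA mean
0.68,0.17,ICRS-only subgroup preoperative CDVA mean
0.53,0.28,ICRS+CXL subgroup preoperative CDVA mean
0.78,0.11,ICRS-only subgroup postoperative CDVA mean
0.70,0.15,ICRS+CXL subgroup postoperative CDVA mean
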