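model,cohort,n_relapse,n_ccr,accuracy,ppv,npv,sensitivity,specificity,p_printed,p_excl_training
5-GC,Training,22,28,82,81,83,77,86,9.4e-06,
5-GC,Validation,9,25,79,100,78,22,100,0.064,
5-GC,COG 9404,14,30,75,71,76,36,93,0.025,
5-GC,POG 8704,17,24,68,83,66,29,96,0.066,
5-GC,Combined,62,107,76,81,75,47,93,1.5e-09,1.2e-04
NFkB,Training,22,28,76,71,81,77,75,4.8e-04,
NFkB,COG 9404,14,30,77,83,76,36,97,0.009,
NFkB,POG 8704,17,24,56,44,59,24,79,1,
NFkB,Combined,53,82,70,67,72,49,84,7.2e-05,0.073
Wnt/Ca2+/cGMP,Training,22,28,76,75,77,68,82,4.6e-04,
Wnt/Ca2+/cGMP,COG 9404,14,30,75,67,77,43,90,0.019,
Wnt/Ca2+/cGMP,POG 8704,17,24,68,63,72,59,75,0.05,
Wnt/Ca2+/cGMP,Combined,53,82,73,69,76,58,83,8.7e-07,0.0011
Cell Adhesion,Training,22,28,82,84,81,73,89,8.6e-06,
Cell Adhesion,COG 9404,14,30,75,62,81,57,83,0.012,
Cell Adhesion,POG 8704,17,24,85,87,85,76,92,1.1e-05,
Cell Adhesion,Combined,53,82,81,79,82,70,88,8.2e-12,4.5e-07
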