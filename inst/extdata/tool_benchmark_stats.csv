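tool,recall,precision,specificity,accuracy
Mut. Assessor,0.89,0.96,0.67,0.87
Meta-SNP,0.85,0.96,0.67,0.83
PredictSNP,0.78,0.95,0.67,0.77
PolyPhen-1,0.78,0.95,0.67,0.77
PolyPhen-2,0.85,0.96,0.67,0.83
PhD-SNP,0.85,0.96,0.67,0.83
PON-P2,0.89,0.96,0.67,0.87
PhD-SNPg,1.00,0.96,0.67,0.97
NEI Mut. Search,0.81,0.96,0.67,0.80
BayesDel_addAF,1.00,0.96,0.67,0.97
BayesDel_noAF,1.00,0.96,0.67,0.97
ClinPred,0.89,1.00,1.00,0.90
LRT,0.96,0.96,0.67,0.93
MetaRNN,1.00,1.00,1.00,1.00
MetaSVM,0.96,0.96,0.67,0.93
REVEL,1.00,0.96,0.67,0.97
CADD,1.00,0.96,0.67,0.97
Eigen-PC,1.00,0.96,0.67,0.97
Eigen,0.96,0.96,0.67,0.93
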