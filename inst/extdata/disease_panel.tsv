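phenotype	n_case	n_control	prevalence_pct
Rheumatoid arthritis	8040	329098	2.38
Psoriasis	6595	330543	1.96
Gout	9462	327676	2.81
Inflammatory bowel disease	3703	333435	1.10
Asthma	48234	288904	14.31
All-cause dementia	4987	332151	1.48
Alzheimer's disease	2060	335078	0.61
Atrial fibrillation	25839	311299	7.66
Breast cancer	14870	181027	7.59
Colorectal cancer	6869	330269	2.04
Coronary artery disease	23184	313954	6.88
Type 2 diabetes	25589	311549	7.59
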