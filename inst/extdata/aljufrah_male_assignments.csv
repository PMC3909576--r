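collection_site,male_code,candidate_cultivar,pair_lod
Sokna,SMM-Q-04,Kathari,9.47
Sokna,SME-Q-03,Tasferit,0.13
Sokna,SMT-Q-01,Tasferit,6.60
Sokna,SMT-Q-02,Sokeri,1.26
Sokna,SSA-Q-01,Deglet,9.87
Sokna,SSA-Q-02,Deglet,1.77
Sokna,SAK-Q-02,Bestian,6.97
Sokna,SAK-Q-03,Sokeri,2.20
Hun,HSM-Q-02,Bestian,1.26
Hun,HRG-Q-01,Tagiat,3.08
Hun,H6I-Q-02,Deglet,1.05
Hun,H6I-Q-03,Tagiat,5.73
Hun,H6E-Q-03,Bamour,1.33
Hun,H3F-Q-03,Tameg,1.26
Hun,H5H-Q-02,Abel,3.45
Hun,H5H-Q-03,Hamria,2.16
Hun,H3H-Q-02,Bestian,1.12
Waddan,WOE-Q-02,Abel,9.15
Waddan,WBH-Q-01,Abel,3.33
Waddan,WBH-Q-02,Sokeri,1.75
Waddan,WFZ-Q-03,Tagiat,9.90
Waddan,WHS-Q-01,Tagiat,3.80
Waddan,W4B-Q-03,Hamria,1.82
Waddan,WBB-B,Tasferit,1.60
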