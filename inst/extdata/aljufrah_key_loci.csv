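locus,prefix,n_labeled_alleles
mPdCIR78,a,10
mPdCIR93,b,7
mPdCIR25,c,6
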