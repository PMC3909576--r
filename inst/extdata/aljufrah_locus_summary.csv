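locus,range_min,range_max,n_alleles,n_genotypes,Hobs,Hexp,n_fixed,fixed_alleles,fixed_in_cultivars
mPdCIR10,138,176,6,13,0.41,0.46,1,154,A;Be;D;Hal;O;S;Tag;Tam
mPdCIR15,142,157,5,15,0.87,0.77,2,142|157,Tag|Z
mPdCIR25,219,257,6,17,0.90,0.76,1,249,Be
mPdCIR32,306,321,5,13,0.71,0.66,2,316|309,S;Z|Tal
mPdCIR70,205,227,9,32,0.91,0.83,1,213,D
mPdCIR78,126,173,11,36,0.85,0.85,2,136|153,Tag|S
mPdCIR85,175,199,8,39,0.83,0.85,2,175|181,O|Hal
mPdCIR93,181,197,7,17,0.77,0.77,1,197,O
PDCAT1,103,123,4,10,0.23,0.63,4,103|105|119|123,Tam;Z|Bes;S|A;D;Hal;S|Tal
PDCAT2,186,209,7,20,0.85,0.79,2,186|206,Z|Bes
PDCAT6,142,172,7,17,0.82,0.71,2,150|158,Z|O
PDCAT8,222,258,6,14,0.78,0.68,2,246|252,S|Tal
PDCAT11,154,177,6,20,0.75,0.79,2,154|159,Z|S
PDCAT14,141,163,9,20,0.42,0.63,1,155,D;Hal;O;Tag;Tal;Tam
PDCAT17,131,157,6,14,0.45,0.63,3,141|147|157,S|A;D;K;N;O|Tal
PDCAT18,123,149,8,29,0.88,0.77,0,,
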