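group,locus,size_min,size_max,allele_number,ho,pic,max_alleles
LT-origin,BPPCT040,115,155,21,1.00,0.274,6
LT-origin,BPPCT034,216,258,17,1.00,0.256,6
LT-origin,BPPCT039,126,171,15,1.00,0.286,5
LT-origin,BPPCT014,185,225,12,0.71,0.243,5
LT-origin,UDP98-407,168,197,11,0.71,0.258,3
LT-origin,PacA33,175,213,13,0.79,0.265,6
LT-origin,BPPCT007,124,161,14,1.00,0.374,6
LT-origin,CPSCT026,166,213,18,1.00,0.280,6
LT-origin,UDP96-005,96,154,19,0.71,0.240,6
R-Plum,BPPCT040,116,147,8,1.00,0.410,5
R-Plum,BPPCT034,216,258,13,1.00,0.308,4
R-Plum,BPPCT039,126,177,13,1.00,0.368,5
R-Plum,BPPCT014,185,225,9,1.00,0.358,5
R-Plum,UDP98-407,164,194,6,0.33,0.343,3
R-Plum,PacA33,168,210,11,1.00,0.333,4
R-Plum,BPPCT007,124,149,11,1.00,0.369,6
R-Plum,CPSCT026,166,210,13,1.00,0.368,3
R-Plum,UDP96-005,104,152,11,0.83,0.414,5
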