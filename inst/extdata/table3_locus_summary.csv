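group,locus,size_min,size_max,allele_number,ho,pic
hybrid,BPPCT040,115,155,26,1.00,0.253
hybrid,BPPCT034,216,256,22,1.00,0.221
hybrid,BPPCT039,124,177,23,1.00,0.251
hybrid,BPPCT014,185,225,14,0.95,0.225
hybrid,UDP98-407,164,225,17,0.80,0.179
hybrid,PacA33,168,221,26,0.82,0.157
hybrid,BPPCT007,124,161,18,1.00,0.279
hybrid,CPSCT026,166,211,20,1.00,0.260
hybrid,UDP96-005,96,154,25,0.77,0.179
parental,BPPCT040,117,155,17,1.00,0.333
parental,BPPCT034,216,250,15,1.00,0.352
parental,BPPCT039,126,177,13,1.00,0.363
parental,BPPCT014,185,221,9,1.00,0.284
parental,UDP98-407,164,198,9,0.50,0.358
parental,PacA33,168,194,8,0.83,0.347
parental,BPPCT007,124,161,12,1.00,0.352
parental,CPSCT026,166,211,13,1.00,0.333
parental,UDP96-005,96,154,13,0.83,0.355
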