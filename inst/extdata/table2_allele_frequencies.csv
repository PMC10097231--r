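locus,allele,category,p_i,printed_rare
BPPCT040,116,common,20,FALSE
BPPCT040,120,common,25,FALSE
BPPCT040,124,common,35,FALSE
BPPCT040,126,common,50,FALSE
BPPCT040,128,common,50,FALSE
BPPCT040,134,common,30,FALSE
BPPCT040,145,common,25,FALSE
BPPCT040,147,common,40,FALSE
BPPCT040,115,unique_lt,5,TRUE
BPPCT040,118,unique_lt,5,TRUE
BPPCT040,119,unique_lt,5,TRUE
BPPCT040,131,unique_lt,5,TRUE
BPPCT040,136,unique_lt,10,TRUE
BPPCT040,138,unique_lt,5,TRUE
BPPCT040,140,unique_lt,10,TRUE
BPPCT040,141,unique_lt,5,TRUE
BPPCT040,144,unique_lt,10,TRUE
BPPCT040,149,unique_lt,5,TRUE
BPPCT040,150,unique_lt,5,TRUE
BPPCT040,153,unique_lt,15,FALSE
BPPCT040,155,unique_lt,15,FALSE
BPPCT034,216,common,75,FALSE
BPPCT034,226,common,25,FALSE
BPPCT034,229,common,10,TRUE
BPPCT034,235,common,20,FALSE
BPPCT034,236,common,15,FALSE
BPPCT034,238,common,10,TRUE
BPPCT034,241,common,55,FALSE
BPPCT034,243,common,20,FALSE
BPPCT034,250,common,15,FALSE
BPPCT034,258,common,15,FALSE
BPPCT034,222,unique_lt,10,TRUE
BPPCT034,227,unique_lt,5,TRUE
BPPCT034,232,unique_lt,5,TRUE
BPPCT034,234,unique_lt,35,FALSE
BPPCT034,237,unique_lt,5,TRUE
BPPCT034,246,unique_lt,10,TRUE
BPPCT034,247,unique_lt,5,TRUE
BPPCT034,225,unique_ref,5,TRUE
BPPCT034,249,unique_ref,5,TRUE
BPPCT034,256,unique_ref,5,TRUE
BPPCT039,126,common,35,FALSE
BPPCT039,129,common,20,FALSE
BPPCT039,131,common,15,FALSE
BPPCT039,132,common,30,FALSE
BPPCT039,136,common,25,FALSE
BPPCT039,143,common,25,FALSE
BPPCT039,145,common,15,FALSE
BPPCT039,150,common,15,FALSE
BPPCT039,153,common,70,FALSE
BPPCT039,171,common,25,FALSE
BPPCT039,128,unique_lt,10,TRUE
BPPCT039,130,unique_lt,10,TRUE
BPPCT039,141,unique_lt,10,TRUE
BPPCT039,163,unique_lt,5,TRUE
BPPCT039,167,unique_lt,10,TRUE
BPPCT039,139,unique_ref,5,TRUE
BPPCT039,159,unique_ref,5,TRUE
BPPCT039,177,unique_ref,10,TRUE
BPPCT014,185,common,85,FALSE
BPPCT014,202,common,20,FALSE
BPPCT014,204,common,45,FALSE
BPPCT014,214,common,15,FALSE
BPPCT014,215,common,20,FALSE
BPPCT014,216,common,15,FALSE
BPPCT014,218,common,10,TRUE
BPPCT014,223,common,10,TRUE
BPPCT014,225,common,25,FALSE
BPPCT014,203,unique_lt,15,FALSE
BPPCT014,208,unique_lt,5,TRUE
BPPCT014,221,unique_lt,5,TRUE
UDP98-407,181,common,30,FALSE
UDP98-407,187,common,25,FALSE
UDP98-407,194,common,20,FALSE
UDP98-407,168,unique_lt,10,TRUE
UDP98-407,172,unique_lt,5,TRUE
UDP98-407,179,unique_lt,25,TRUE
UDP98-407,186,unique_lt,5,TRUE
UDP98-407,189,unique_lt,5,TRUE
UDP98-407,191,unique_lt,15,FALSE
UDP98-407,193,unique_lt,15,FALSE
UDP98-407,197,unique_lt,5,TRUE
UDP98-407,164,unique_ref,5,TRUE
UDP98-407,177,unique_ref,5,TRUE
UDP98-407,185,unique_ref,5,TRUE
PacA33,175,common,50,FALSE
PacA33,177,common,15,FALSE
PacA33,185,common,30,FALSE
PacA33,193,common,15,FALSE
PacA33,194,common,30,FALSE
PacA33,196,common,10,FALSE
PacA33,209,common,10,TRUE
PacA33,179,unique_lt,10,TRUE
PacA33,183,unique_lt,20,FALSE
PacA33,191,unique_lt,15,FALSE
PacA33,192,unique_lt,5,TRUE
PacA33,202,unique_lt,5,TRUE
PacA33,213,unique_lt,10,TRUE
PacA33,168,unique_ref,5,TRUE
PacA33,198,unique_ref,5,TRUE
PacA33,206,unique_ref,5,TRUE
PacA33,210,unique_ref,5,TRUE
BPPCT007,124,common,40,FALSE
BPPCT007,126,common,20,FALSE
BPPCT007,128,common,40,FALSE
BPPCT007,130,common,55,FALSE
BPPCT007,134,common,60,FALSE
BPPCT007,136,common,20,FALSE
BPPCT007,138,common,45,FALSE
BPPCT007,140,common,50,FALSE
BPPCT007,142,common,20,FALSE
BPPCT007,144,common,10,TRUE
BPPCT007,149,common,60,FALSE
BPPCT007,134,unique_lt,10,TRUE
BPPCT007,146,unique_lt,10,TRUE
BPPCT007,151,unique_lt,30,FALSE
BPPCT007,161,unique_lt,5,TRUE
CPSCT026,166,common,55,FALSE
CPSCT026,175,common,25,FALSE
CPSCT026,183,common,25,FALSE
CPSCT026,188,common,10,TRUE
CPSCT026,189,common,80,FALSE
CPSCT026,193,common,35,FALSE
CPSCT026,196,common,25,FALSE
CPSCT026,199,common,35,FALSE
CPSCT026,200,common,20,FALSE
CPSCT026,202,common,55,FALSE
CPSCT026,204,common,25,FALSE
CPSCT026,210,common,15,FALSE
CPSCT026,173,unique_lt,5,TRUE
CPSCT026,195,unique_lt,15,FALSE
CPSCT026,197,unique_lt,15,FALSE
CPSCT026,208,unique_lt,5,TRUE
CPSCT026,211,unique_lt,5,TRUE
CPSCT026,213,unique_lt,5,TRUE
CPSCT026,185,unique_ref,5,TRUE
UDP96-005,104,common,25,FALSE
UDP96-005,105,common,10,TRUE
UDP96-005,107,common,20,FALSE
UDP96-005,112,common,30,FALSE
UDP96-005,115,common,20,FALSE
UDP96-005,125,common,15,FALSE
UDP96-005,137,common,15,FALSE
UDP96-005,148,common,35,FALSE
UDP96-005,152,common,30,FALSE
UDP96-005,96,unique_lt,10,TRUE
UDP96-005,120,unique_lt,10,TRUE
UDP96-005,124,unique_lt,10,TRUE
UDP96-005,128,unique_lt,5,TRUE
UDP96-005,130,unique_lt,10,TRUE
UDP96-005,132,unique_lt,5,TRUE
UDP96-005,134,unique_lt,5,TRUE
UDP96-005,139,unique_lt,10,TRUE
UDP96-005,142,unique_lt,10,TRUE
UDP96-005,154,unique_lt,15,FALSE
UDP96-005,127,unique_ref,5,FALSE
UDP96-005,150,unique_ref,10,FALSE
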