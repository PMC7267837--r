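cell_id,GeneA,GeneB,GeneC,GeneD,GeneE,GeneF
AAAC-1,4,1,0,0,0,0
AAAG-1,0,0,7,2,0,0
AACT-1,5,0,0,0,3,0
AAGG-1,0,6,0,8,0,1
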