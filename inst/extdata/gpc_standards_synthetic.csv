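name,mw_da,ve_ml
BSA,66430,1.62
carbonic anhydrase,29000,1.89
cytochrome c,12384,2.17
aprotinin,6511,2.38
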