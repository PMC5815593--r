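group,IPP,HPCP,IPCP
autochorous,1,2,5
anemochorous,5,10,9
zoo-small,17,18,77
zoo-medium,15,8,35
zoo-large,2,7,18
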