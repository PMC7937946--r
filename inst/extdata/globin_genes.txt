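HBA1
HBA2
HBB
HBD
HBG1
HBG2
HBE1
HBZ
HBM
HBQ1
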