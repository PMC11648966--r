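# Representative 12-composition human O-glycan database (core 1/2 structures
# with fucosylation and sialylation). One Byonic-style composition per line;
# optional "% mass" annotations are checked against computed masses.
HexNAc(1)
HexNAc(1)Hex(1) % 365.1322
HexNAc(1)NeuAc(1)
HexNAc(1)Hex(1)Fuc(1)
HexNAc(1)Hex(1)NeuAc(1)
HexNAc(1)Hex(1)NeuAc(2)
HexNAc(2)
HexNAc(2)Hex(1)
HexNAc(2)Hex(2)
HexNAc(2)Hex(1)NeuAc(1)
HexNAc(2)Hex(2)NeuAc(1)
HexNAc(2)Hex(2)NeuAc(2)
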