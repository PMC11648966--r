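# Oxonium diagnostic-ion rules: residues<TAB>ion m/z list<TAB>min summed relative intensity
# A glycan box is considered for a spectrum only if, for every rule whose
# residues the box contains, the listed ions are present in the collisional
# scan with summed base-peak-relative intensity at or above the threshold.
HexNAc(1)Hex(1)	366.1395	0.05
Hex(1)	163.0601,145.0495	0.05
NeuAc(1)	274.0921,292.1027	0.05
NeuGc(1)	290.0870,308.0976	0.05
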