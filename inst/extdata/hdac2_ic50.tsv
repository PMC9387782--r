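ligand	ic50_nM
LLX	27
SAHA	251
20Y	56.3
IWX	62
6EZ	168
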