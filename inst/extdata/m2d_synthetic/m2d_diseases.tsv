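doid	name
DOID:0001	synthetic carcinoma
DOID:0002	synthetic cardiomyopathy
DOID:0003	synthetic neuropathy
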