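key	score
GC/GC/GC	1.0
CG/GC/CG	0.95
AU/GC/UA	0.775
UA/CG/GU	0.65
GU/AU/UG	0.425
-C/GC/AU	0.6625
AU/-G/CG	0.425
-U/UA/-A	0.275
UG/UG/UG	0.2
-A/-C/-G	0.0625
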