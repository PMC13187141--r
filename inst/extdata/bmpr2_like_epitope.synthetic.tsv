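group	ref_pos_1based	contact_type
Aloop	40	polar
Aloop	42	polar
Aloop	44	hydrophobic
Aloop	46	polar
Aloop	48	hydrophobic
Aloop	50	polar
F3loop	70	polar
F3loop	73	hydrophobic
F3loop	75	polar
F3loop	77	polar
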