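group	ref_pos_1based	contact_type
F1	22	polar
F1	24	hydrophobic
F1	26	polar
F1	28	polar
F1	30	hydrophobic
F3	72	polar
F3	74	hydrophobic
F3	76	polar
F3	78	polar
Cterm	100	polar
Cterm	102	polar
Cterm	104	hydrophobic
Cterm	106	polar
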