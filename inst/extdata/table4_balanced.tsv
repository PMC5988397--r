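functional	act_hydrolysis	rxn_hydrolysis	act_transfructosylation	rxn_transfructosylation
B3LYP	49.0	18.4	32.3	17.5
M06-2X	65.4	32.8	30.4	11.2
B97D	64.0	36.7	21.9	10.2
wB97XD	28.3	-4.0	27.4	10.8
MPWB1K	56.1	24.8	30.9	14.2
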