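model	charge	description
QM1	-2	Side-chain atoms of Asp60 (nucleophile), Asp191 (TS stabilizer), Glu292 (acid/base), and substrate (same QM region as the QM/MM calculations)
QM2	-2	QM1 plus side chains of Phe118, Asp119, His144, Arg190, Glu318, Ser329, His332, Tyr369, Tyr404, Glu405 and backbone of Ile143
QM3	-2	QM2 plus water molecules; designed to keep the total atom count (242 atoms) equal across the reaction steps
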