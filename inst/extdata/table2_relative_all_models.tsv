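label	step	model	method	delta_e_kcal
ES	fructosylation	QM1	cpcm	0.0
TS1	fructosylation	QM1	cpcm	18.2
IM1	fructosylation	QM1	cpcm	0.6
IM2	hydrolysis	QM1	cpcm	0.0
TS2	hydrolysis	QM1	cpcm	19.4
PC2	hydrolysis	QM1	cpcm	-12.3
IM3	transfructosylation	QM1	cpcm	0.0
TS3	transfructosylation	QM1	cpcm	24.9
PC3	transfructosylation	QM1	cpcm	1.1
ES	fructosylation	QM1	gas	0.0
TS1	fructosylation	QM1	gas	12.1
IM1	fructosylation	QM1	gas	-0.8
IM2	hydrolysis	QM1	gas	0.0
TS2	hydrolysis	QM1	gas	13.0
PC2	hydrolysis	QM1	gas	-19.6
IM3	transfructosylation	QM1	gas	0.0
TS3	transfructosylation	QM1	gas	18.0
PC3	transfructosylation	QM1	gas	-6.9
ES	fructosylation	QM2	cpcm	0.0
TS1	fructosylation	QM2	cpcm	19.0
IM1	fructosylation	QM2	cpcm	7.8
IM2	hydrolysis	QM2	cpcm	0.0
TS2	hydrolysis	QM2	cpcm	17.5
PC2	hydrolysis	QM2	cpcm	-14.5
IM3	transfructosylation	QM2	cpcm	0.0
TS3	transfructosylation	QM2	cpcm	22.6
PC3	transfructosylation	QM2	cpcm	7.4
ES	fructosylation	QM2	gas	0.0
TS1	fructosylation	QM2	gas	4.2
IM1	fructosylation	QM2	gas	-5.0
IM2	hydrolysis	QM2	gas	0.0
TS2	hydrolysis	QM2	gas	17.0
PC2	hydrolysis	QM2	gas	-5.3
IM3	transfructosylation	QM2	gas	0.0
TS3	transfructosylation	QM2	gas	17.9
PC3	transfructosylation	QM2	gas	8.2
ES	fructosylation	QM3	cpcm	0.0
TS1	fructosylation	QM3	cpcm	18.6
IM1	fructosylation	QM3	cpcm	9.4
IM2	hydrolysis	QM3	cpcm	0.0
TS2	hydrolysis	QM3	cpcm	15.5
PC2	hydrolysis	QM3	cpcm	-14.7
IM3	transfructosylation	QM3	cpcm	0.0
TS3	transfructosylation	QM3	cpcm	23.0
PC3	transfructosylation	QM3	cpcm	9.0
ES	fructosylation	QM3	gas	0.0
TS1	fructosylation	QM3	gas	7.4
IM1	fructosylation	QM3	gas	0.7
IM2	hydrolysis	QM3	gas	0.0
TS2	hydrolysis	QM3	gas	15.1
PC2	hydrolysis	QM3	gas	-7.5
IM3	transfructosylation	QM3	gas	0.0
TS3	transfructosylation	QM3	gas	19.1
PC3	transfructosylation	QM3	gas	11.2
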