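gene	variant	consequence	af_population	af_control	families	cadd_phred	n_damaging_votes	sift	polyphen	mut_taster	mut_assessor	fathmm_pred	fathmm_mkl
METTL21B	c.620G>A	missense	0.0018	0.0050	Fam1,Fam17,Fam27,Fam32	24.1	4	damaging	damaging	damaging	damaging	benign	benign
DIS3L2	c.1651_1652insGGG	missense	0.0022	0	Fam17,Fam26,Fam31	1.4	NA	NA	NA	NA	NA	NA	NA
PPP6R2	c.1421G>A	missense	0.0049	0.0076	Fam1,Fam2,Fam35	23.5	4	damaging	damaging	damaging	damaging	benign	benign
PPP6R2	c.2345G>A	missense	0.0049	0.0094	Fam1,Fam2,Fam35	14.8	2	damaging	damaging	benign	benign	benign	benign
TM4SF19	c.586A>G	missense	0.0043	0.0066	Fam19,Fam32,Fam42	22.5	3	damaging	damaging	damaging	benign	benign	benign
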