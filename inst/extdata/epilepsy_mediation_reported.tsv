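immune_cell	metabolite	outcome	proportion_pct	ci_low_pct	ci_high_pct	p
memory B cell %lymphocyte	adenosine 5'-monophosphate (AMP) levels	epilepsy	9.34	0.050	18.6	0.049
CD45RA+ CD8br AC	DMTPA levels	epilepsy	-1.64	-3.15	-0.135	0.033
CD45RA+ CD8br AC	X-12680 levels	epilepsy	-3.61	-7.12	-0.098	0.044
DN (CD4-CD8-) AC	3-hydroxyoctanoylcarnitine (2) levels	epilepsy	-15.3	-30.6	-0.008	0.049
CD39+ CD8br %T cell	branched-chain/straight-chain/cyclopropyl 10:1 fatty acid (1) levels	epilepsy	-9.43	-18.4	-0.467	0.039
CD3 on Naive CD4+	1-oleoyl-GPC (18:1) levels	epilepsy	-11.2	-22	-0.535	0.040
FSC-A on myeloid DC	1-(1-enyl-stearoyl)-2-linoleoyl-GPE (p-18:0/18:2) levels	epilepsy	5.63	0.668	10.6	0.026
FSC-A on myeloid DC	X-12544 levels	epilepsy	-8	-15.1	-0.856	0.028
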