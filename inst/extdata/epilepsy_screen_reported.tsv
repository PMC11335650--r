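trait	trait_class	outcome	or	ci_low	ci_high	p	ci_precision_ok
CD45RA+ CD8br AC	immune_cell	epilepsy	0.926	0.869	0.988	0.020	TRUE
CD39+ CD8br %T cell	immune_cell	epilepsy	0.928	0.883	0.975	0.003	TRUE
PDL-1 on CD14+ CD16- monocyte	immune_cell	epilepsy	0.940	0.886	0.997	0.039	TRUE
IgD+ CD24+ %B cell	immune_cell	epilepsy	0.950	0.904	0.998	0.041	TRUE
SSC-A on HLA DR+ NK	immune_cell	epilepsy	1.026	1.002	1.050	0.031	TRUE
CD24 on transitional	immune_cell	epilepsy	1.038	1.000	1.077	0.045	FALSE
IgD+ CD38dim %B cell	immune_cell	epilepsy	1.044	1.000	1.091	0.049	FALSE
1-oleoyl-GPC (18:1) levels	metabolite	epilepsy	0.904	0.839	0.973	0.007	TRUE
DMTPA levels	metabolite	epilepsy	0.921	0.867	0.978	0.008	TRUE
1-oleoyl-GPI (18:1) levels	metabolite	epilepsy	0.909	0.847	0.976	0.008	TRUE
1-(1-enyl-stearoyl)-2-linoleoyl-GPE (p-18:0/18:2) levels	metabolite	epilepsy	0.916	0.869	0.966	0.001	TRUE
cholate levels	metabolite	epilepsy	1.123	1.039	1.213	0.003	TRUE
threonine levels	metabolite	epilepsy	1.068	1.017	1.121	0.008	TRUE
adenosine 5'-monophosphate (AMP) levels	metabolite	epilepsy	1.144	1.051	1.245	0.002	TRUE
IgD+ CD24+ %B cell -> threonine levels	immune_to_metabolite	threonine levels	1.091	1.023	1.164	0.008	TRUE
memory B cell %lymphocyte -> AMP levels	immune_to_metabolite	AMP levels	0.967	0.936	0.999	0.042	TRUE
DN (CD4-CD8-) AC -> 3-hydroxyoctanoylcarnitine (2) levels	immune_to_metabolite	3-hydroxyoctanoylcarnitine (2) levels	0.930	0.878	0.985	0.013	TRUE
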