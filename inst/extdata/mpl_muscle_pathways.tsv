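pathway	pathway_id	subgroup	n_genes	acute_unique	acute_fc_pct	acute_total_fp_pct	acute_response	chronic_unique	chronic_fc_pct	chronic_total_fp_pct	chronic_response
Arginine and proline metabolism	rno00330	Amino acid metabolism	52	9	17	42	Receptor-mediated	17	33	56	Receptor-mediated/tolerance
Glutathione metabolism	rno00480	Amino acid metabolism	69	10	14	69	Receptor-mediated	22	32	72	Receptor-mediated/tolerance
Apoptosis	rno04210	Cell growth and death	141	23	16	61	Receptor-mediated	38	27	55	Receptor-mediated/tolerance
Cellular senescence	rno04218	Cell growth and death	189	24	13	57	Receptor-mediated	44	23	69	Receptor-mediated/tolerance
Ferroptosis	rno04216	Cell growth and death	41	9	22	49	Receptor-mediated	15	37	72	Tolerance
Regulation of actin cytoskeleton	rno04810	Cell motility	223	21	9	47	Receptor-mediated	48	22	71	Receptor-mediated/tolerance
Adipocytokine signaling pathway	rno04920	Endocrine system	74	14	19	57	Receptor-mediated/biosignal-mediated	20	27	55	Tolerance
Glucagon signaling pathway	rno04922	Endocrine system	103	11	11	65	Receptor-mediated	32	31	58	Receptor-mediated/tolerance
GnRH signaling pathway	rno04912	Endocrine system	94	12	13	60	Receptor-mediated	29	31	76	Biosignal-mediated/tolerance
Insulin signaling pathway	rno04910	Endocrine system	138	18	13	50	Receptor-mediated	43	31	73	Receptor-mediated/tolerance
Oxytocin signaling pathway	rno04921	Endocrine system	157	21	13	58	Receptor-mediated	40	25	57	Receptor-mediated/tolerance
PPAR signaling pathway	rno03320	Endocrine system	82	15	18	61	Receptor-mediated	21	26	61	Receptor-mediated/tolerance
Prolactin signaling pathway	rno04917	Endocrine system	74	13	18	61	Receptor-mediated	18	24	48	Biosignal-mediated/tolerance
Thyroid hormone signaling pathway	rno04919	Endocrine system	118	21	18	41	Receptor-mediated	30	25	55	Tolerance
Proteasome	rno03050	Folding, sorting and degradation	48	14	29	62	Biosignal-mediated	30	63	87	Tolerance
Fatty acid degradation	rno00071	Lipid metabolism	47	11	23	44	Biosignal-mediated	18	38	70	Tolerance
Fatty acid metabolism	rno01212	Lipid metabolism	59	12	20	59	Receptor-mediated	19	32	68	Tolerance
AMPK signaling pathway	rno04152	Signal transduction	127	16	13	50	Receptor-mediated	36	28	58	Tolerance
cGMP-PKG signaling pathway	rno04022	Signal transduction	172	19	11	54	Receptor-mediated	38	22	53	Receptor-mediated/tolerance
ErbB signaling pathway	rno04012	Signal transduction	88	11	13	70	Receptor-mediated	23	26	61	Tolerance
FoxO signaling pathway	rno04068	Signal transduction	134	16	12	61	Receptor-mediated	43	32	68	Biosignal-mediated/tolerance
HIF-1 signaling pathway	rno04066	Signal transduction	107	16	15	55	Receptor-mediated	35	33	67	Receptor-mediated/tolerance
MAPK signaling pathway	rno04010	Signal transduction	300	39	13	59	Receptor-mediated/biosignal-mediated	68	23	81	Receptor-mediated/tolerance
PI3K-Akt signaling pathway	rno04151	Signal transduction	349	45	13	51	Receptor-mediated	73	21	56	Receptor-mediated/tolerance
Rap1 signaling pathway	rno04015	Signal transduction	213	28	13	54	Receptor-mediated	44	21	67	Receptor-mediated/tolerance
TGF-beta signaling pathway	rno04350	Signal transduction	93	11	12	47	Biosignal-mediated	23	25	54	Receptor-mediated/tolerance
VEGF signaling pathway	rno04370	Signal transduction	58	14	24	57	Receptor-mediated/biosignal-mediated	20	34	83	Receptor-mediated/tolerance
Autophagy - animal	rno04140	Transport and catabolism	134	16	12	70	Receptor-mediated	45	34	59	Tolerance
Peroxisome	rno04146	Transport and catabolism	88	11	13	47	Receptor-mediated	24	27	77	receptor-mediated/tolerance
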