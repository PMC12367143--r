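enzyme	step_id	k_forward	k_backward	units
cysRS	aa_bind_E	0.182085232608817	22.9679614540092	bi/uni
cysRS	atp_bind_E	1	1311.65730689041	bi/uni
cysRS	atp_bind_EA	1	1311.65730689041	bi/uni
cysRS	aa_bind_ET	0.182085232608817	22.9679614540092	bi/uni
cysRS	act	501.275180564801	227.169767696227	uni/uni
cysRS	ppi_rel	110.051869406173	0.05	uni/bi
cysRS	trna_bind_E	30	2.56485609261383	bi/uni
cysRS	trna_bind_EA	30	2.56485609261383	bi/uni
cysRS	trna_bind_ET	30	2.56485609261383	bi/uni
cysRS	trna_bind_EAT	30	2.56485609261383	bi/uni
cysRS	trna_bind_ED	8.45714285714286	36.6662648597216	bi/uni
cysRS	aa_bind_ER	0.191230709824164	27.3074393789926	bi/uni
cysRS	atp_bind_ER	1	300	bi/uni
cysRS	atp_bind_EAR	1	300	bi/uni
cysRS	aa_bind_ETR	0.191230709824164	27.3074393789926	bi/uni
cysRS	act_trna	501.275180564801	227.169767696227	uni/uni
cysRS	ppi_rel_pre	110.051869406173	0.05	uni/bi
cysRS	tran_ppi	67.1934848929283	0.01	uni/uni
cysRS	ppi_rel_post	110.051869406173	0.05	uni/bi
cysRS	tran	15.950887487171	0.01	uni/uni
cysRS	amp_rel	155.37747049157	1e-04	uni/bi
cysRS	prod_rel	3.41896899766121	1e-04	uni/bi
cysRS	atp_bind_ERs	1	300	bi/uni
cysRS	prod_rel_atp	3.41896899766121	1e-04	uni/bi
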