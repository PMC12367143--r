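enzyme	step_id	k_forward	k_backward	units
hisRS	aa_bind_E	0.486080466827684	73.5911116437506	bi/uni
hisRS	atp_bind_E	1	2199.84205356354	bi/uni
hisRS	atp_bind_EA	1	2199.84205356354	bi/uni
hisRS	aa_bind_ET	0.486080466827684	73.5911116437506	bi/uni
hisRS	act	765.969895288149	358.221897808552	uni/uni
hisRS	ppi_rel	108.212054087176	0.05	uni/bi
hisRS	trna_bind_E	30	0.3	bi/uni
hisRS	trna_bind_EA	30	0.3	bi/uni
hisRS	trna_bind_ET	30	0.3	bi/uni
hisRS	trna_bind_EAT	30	0.3	bi/uni
hisRS	trna_bind_ED	30	16.2462266261915	bi/uni
hisRS	aa_bind_ER	0.979183405166286	0.979183405166286	bi/uni
hisRS	atp_bind_ER	1	300	bi/uni
hisRS	atp_bind_EAR	1	300	bi/uni
hisRS	aa_bind_ETR	0.979183405166286	0.979183405166286	bi/uni
hisRS	act_trna	765.969895288149	358.221897808552	uni/uni
hisRS	ppi_rel_pre	108.212054087176	0.05	uni/bi
hisRS	tran_ppi	19.5331510331786	0.01	uni/uni
hisRS	ppi_rel_post	108.212054087176	0.05	uni/bi
hisRS	tran	19.5331510331786	0.01	uni/uni
hisRS	amp_rel	13.9295088850242	1e-04	uni/bi
hisRS	aa_bind_s2	0.979183405166286	0.979183405166286	bi/uni
hisRS	atp_bind_s2	1	300	bi/uni
hisRS	atp_bind_s2b	1	300	bi/uni
hisRS	aa_bind_s2b	0.979183405166286	0.979183405166286	bi/uni
hisRS	act_s2	765.969895288149	358.221897808552	uni/uni
hisRS	ppi_rel_s2	108.212054087176	0.05	uni/bi
hisRS	prod_rel_flip_pp	175.131916479522	1e-04	uni/bi
hisRS	prod_rel_flip	175.131916479522	1e-04	uni/bi
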