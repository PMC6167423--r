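# Synthetic curated synonym table: NMR metabolite names from the packaged
# shift tables mapped to compartmentless BiGG-style network ids. Constructed
# for this package; not taken from any published mapping.
name	network_id
Alanine	ala_L
AMP	amp
Arginine	arg_L
Asparagine	asn_L
Citrate	cit
Creatine	creat
Dimethylglycine	dmgly
Glutamine	gln_L
Reduced glutathione	gthrd
Glycerol	glyc
Glycerophosphocholine	g3pc
Isoleucine	ile_L
Isopropanol	2ppoh
Lactate	lac_L
Leucine	leu_L
Lysine	lys_L
Proline	pro_L
Serine	ser_L
Succinate	succ
Valine	val_L
Acetate	ac
Choline	chol
Ethanolamine	etha
Formate	for
Glucose	glc_D
Glutamate	glu_L
Glycine	gly
Phosphocholine	cholp
Tyrosine	tyr_L
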