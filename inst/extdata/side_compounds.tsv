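id	name
h2o	water
h	proton
atp	ATP
adp	ADP
amp	AMP
nad	NAD+
nadh	NADH
nadp	NADP+
nadph	NADPH
co2	carbon dioxide
pi	phosphate
ppi	diphosphate
o2	oxygen
coa	coenzyme A
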