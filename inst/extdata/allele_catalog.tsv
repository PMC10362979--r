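# ACE resistance-allele catalog: residue combinations at diagnostic
# positions 260/316/342/407, field allele names I-VI, laboratory allele
# synonyms (V1-V15 naming) and sensitivity class.
res260	res316	res342	res407	allele	lab_alleles	class
V	A	V	Y	I	V14	insensitive
L	A	G	Y	II	-	putative_insensitive
L	A	A	Y	III	V15	insensitive
L	A	G	F	IV	-	putative_insensitive
V	A	A	Y	V	V10	insensitive
V	A	G	F	VI	V1-V9,V12,V13	sensitive
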