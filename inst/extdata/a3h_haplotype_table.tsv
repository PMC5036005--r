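# Default APOBEC3H haplotype-defining allele table (synthetic single-base
# encoding of the protein-level dichotomies: codon 15 Asn presence vs the
# destabilizing deletion carried by haplotypes III/IV/VI, tagged here by a
# biallelic marker; codon 105 Gly [G] vs Arg [C]; codons 121 and 178
# distinguish the remaining stable haplotypes). Site-by-site combinations
# for haplotypes V and VII are not uniquely documented; this default table
# is overridable via the haplotype_table argument.
site	haplotype	base
c15	I	A
c15	II	A
c15	III	G
c15	IV	G
c15	V	A
c15	VI	G
c15	VII	A
c105	I	G
c105	II	C
c105	III	C
c105	IV	C
c105	V	C
c105	VI	C
c105	VII	C
c121	I	A
c121	II	G
c121	III	G
c121	IV	A
c121	V	A
c121	VI	G
c121	VII	G
c178	I	A
c178	II	T
c178	III	A
c178	IV	A
c178	V	A
c178	VI	T
c178	VII	A
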