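# Fluorochrome-labelled oligonucleotide FISH probes of the common bean
# karyotyping system (24-26 nt). CentPv1_B was synthesized with both FAM
# and TEX615 labels; the TEX615 form is the one deployed in the final
# karyotyping cocktail and is listed here.
name	sequence	fluorophore	target
CentPv1	CACATGAAATTGTTTTTCAAAGATA	Cy5	centromere
CentPv2	CAATAAATTCATGCAACTACCACAA	TEX615	centromere
CentPv1_A	GGTTTTTCAAGGGTGTATCATAGGT	FAM	centromere
CentPv2_A	CCAATGTCTATCACTACTCTTTGACA	FAM	centromere
CentPv1_B	TCAAAGGTATTATCACAAGTGTTCGA	TEX615	centromere
CentPv1_C	TTCATTCATAAGTGTTTCAATCAATT	TEX615	centromere
CentPv1_D	ATCTATCATAAGTGTTTCAATCAGTT	TEX615	centromere
khipu	GACACAGTGACGAATGTCTGGTAAA	TEX615	subtelomere
5S_rDNA	GCACTAATGCACCGGATCCCATCA	TEX615	rDNA_locus
18S_rDNA	GTAATTCCAGCTCCAATAGCGTATA	FAM	rDNA_locus
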