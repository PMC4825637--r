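# Chromosome-specific single/low-copy BAC clones of the common bean
# karyotyping system, with their anchored coordinates on the
# pseudo-chromosomes (1-based inclusive), insert length, physical position
# (midpoint percent of the pseudo-chromosome) and total repeat content.
chromosome	linkage_group	clone	bng_marker	first_base	last_base	insert_length	physical_position_percent	repeat_content_percent
1	H	0043E17	Bng083	51533991	51677621	143631	98.85	15.47
2	D	0073I08	NA	42399450	42539858	140409	86.6	10.05
3	C	0084M03	NA	50068422	50162332	93911	95.85	15.14
4	B	0095D15	NA	44627451	44745580	118130	97.23	14.38
5	E	0101A23	Bng162	40054960	40179280	124321	98.28	15.26
6	G	0043E14	NA	29436487	29562452	125966	92.25	9.48
7	A	0100C06	Bng042	3452024	3577941	125918	6.79	12.48
8	F	0102L19	Bng139	172969	320543	147575	0.41	11.41
9	K	0100J23	NA	21306679	21417904	111226	57.01	16.62
10	I	0103D09	NA	41338907	41446050	107144	95.65	12.89
11	J	0033F21	Bng025	6754339	6864292	109954	13.33	19.42
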