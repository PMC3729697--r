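# Haplogroup definition tree for mtDNA haplogroups I (within N1a1b) and W,
# rooted at haplogroup N, motifs relative to rCRS.  source=printed/curated:
# motifs documented in the phylogenetic literature.  source=placeholder:
# SYNTHETIC single-site stand-in markers (positions 5001+7k) for clades
# whose real defining mutations are not reproduced here; they keep the
# tree structurally complete but are not PhyloTree motifs.
name	parent	motif	source
N		-	root
N1	N	5001	placeholder
N1a	N1	5008	placeholder
N1a1	N1a	5015	placeholder
N1a1b	N1a1	5022	placeholder
N1a1b1	N1a1b	143 710 10790	printed
N1a1b1a	N1a1b1	5029	placeholder
N1a1b1a1	N1a1b1a	5036	placeholder
I	N1a1b	10034 16129	printed
I1	I	5043	placeholder
I1a	I1	3447 8616T 16172	printed
I1a1	I1a	203	printed
I1a1a	I1a1	5050	placeholder
I1a1b	I1a1	5057	placeholder
I1a1c	I1a1	5064	placeholder
I1a1d	I1a1	5071	placeholder
I1b	I1	5078	placeholder
I1c	I1	5085	placeholder
I1c1	I1c	16264 16270 16319 16362	curated
I1c1a	I1c1	5092	placeholder
I2'3	I	152 207	printed
I2	I2'3	5099	placeholder
I2a	I2	5106	placeholder
I2a1	I2a	5113	placeholder
I2b	I2	5120	placeholder
I2c	I2	5127	placeholder
I2d	I2	5134	placeholder
I2e	I2	5141	placeholder
I3	I2'3	5148	placeholder
I3a	I3	5155	placeholder
I3a1	I3a	5162	placeholder
I3b	I3	5169	placeholder
I3c	I3	5176	placeholder
I4	I	5183	placeholder
I4a	I4	5190	placeholder
I4a1	I4a	5197	placeholder
I4b	I4	5204	placeholder
I5	I	5211	placeholder
I5a	I5	5218	placeholder
I5a1	I5a	5225	placeholder
I5a2	I5a	5232	placeholder
I5a2a	I5a2	5239	placeholder
I5a3	I5a	5246	placeholder
I5a4	I5a	5253	placeholder
I5b	I5	5260	placeholder
I6	I	5267	placeholder
I6a	I6	5274	placeholder
I6b	I6	5281	placeholder
I7	I	5288	placeholder
N2	N	16482	curated
W	N2	195@ 204 207 1243 3505 5460 8251 8994 11947 15884C 16292	printed
W1	W	5295	placeholder
W1a	W1	5302	placeholder
W1b	W1	5309	placeholder
W1b1	W1b	5316	placeholder
W1c	W1	5323	placeholder
W1c1	W1c	5330	placeholder
W1e	W1	5337	placeholder
W1f	W1	5344	placeholder
W1g	W1	5351	placeholder
W3	W	1406	printed
W3a	W3	5358	placeholder
W3a1	W3a	5365	placeholder
W3a1a	W3a1	5372	placeholder
W3a1a1	W3a1a	5379	placeholder
W3a1a2	W3a1a	5386	placeholder
W3a1b	W3a1	5393	placeholder
W3a1c	W3a1	5400	placeholder
W3a2	W3a	5407	placeholder
W3b	W3	5414	placeholder
W3b1	W3b	5421	placeholder
W4	W	5428	placeholder
W4a	W4	5435	placeholder
W5	W	5442	placeholder
W5a	W5	5449	placeholder
W5a1	W5a	5456	placeholder
W5a1a	W5a1	5463	placeholder
W5a1a1	W5a1a	5470	placeholder
W5a1a1a	W5a1a1	5477	placeholder
W5a2	W5a	5484	placeholder
W5b	W5	5491	placeholder
W6	W	4093 8614 16325	printed
W6a	W6	5498	placeholder
W6b	W6	5505	placeholder
W6c	W6	5512	placeholder
W7	W	185	printed
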