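category	root_total	root_unique	leaf_total	leaf_unique	flower_total	flower_unique	seed_total	seed_unique
protein_coding	989288	38231	861761	36576	799267	39707	840605	38459
noncoding_est	4692205	131039	4401161	122760	3862859	133855	4228824	120271
rRNA	916073	26320	584814	23521	627592	23344	1066465	26117
tRNA	1531792	15873	858608	13740	1851199	16072	4577493	19705
snRNA	7116	987	6963	830	24549	1199	111365	1678
snoRNA	13180	1148	6948	961	9133	1128	27606	1399
miRNA	1583670	2376	3506031	2661	1703039	2335	2567995	2466
other_sRNA	73124	2897	50041	2750	56033	2759	115409	3117
unmatched	6403763	945604	5318140	913921	5901112	986441	5032560	834739
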