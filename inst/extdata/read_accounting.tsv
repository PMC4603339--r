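library	total_reads	clean_reads	subgenome	mapped	ratio_printed	total_ratio_printed	mapped_u	ratio_u_printed	total_ratio_u_printed
Wild-1	23271884	22088185	A	17586172	79.6	86.5	13102552	59.3	74.6
Wild-1	23271884	22088185	B	17813886	80.6	86.5	13140929	59.5	74.6
Wild-2	27577198	26160151	A	20700875	79.1	85.9	15242936	58.3	73.7
Wild-2	27577198	26160151	B	21023950	80.4	85.9	15242734	58.3	73.7
Cultivar-1	17740180	16773599	A	13527727	80.6	87.4	9474682	56.5	71.3
Cultivar-1	17740180	16773599	B	13783371	82.2	87.4	9535891	56.9	71.3
Cultivar-2	29551798	27977895	A	22256822	79.6	86.6	16395908	58.6	74.3
Cultivar-2	29551798	27977895	B	22663043	81.0	86.6	16290987	58.2	74.3
Landrace-1	23082003	21898663	A	16563967	75.6	85.3	14141135	64.6	83.1
Landrace-1	23082003	21898663	B	16971148	77.5	85.3	14275683	65.2	83.1
Landrace-2	26163934	24724657	A	18580284	75.1	84.4	15687853	63.5	81.9
Landrace-2	26163934	24724657	B	19196718	77.6	84.4	15843276	64.1	81.9
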