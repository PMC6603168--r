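name	end	sequence	umi_length
P5-UMI8	5	TTCACGACGTGTTATAATCT	8
P5-UMI12	5	AACCTGGCGCCAGGATGATA	12
P3-UMI8	3	GCGTGCTCTGCTAATAAGAA	8
P3-UMI12	3	TCCTCAGGTGTGGTTATACG	12
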