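soil	time	replicate	n_sequences
Bs	1S	1	2492
Bs	1S	2	10949
Bs	1S	3	6252
Bs	1S	4	9685
Bs	1S	5	11600
Bs	2S	1	9670
Bs	2S	2	9730
Bs	2S	3	11639
Bs	2S	4	12169
Bs	2S	5	7145
Rs	1S	1	6286
Rs	1S	2	13603
Rs	1S	3	9910
Rs	1S	4	10229
Rs	1S	5	9641
Rs	2S	1	8153
Rs	2S	2	6405
Rs	2S	3	6623
Rs	2S	4	12570
Rs	2S	5	8816
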