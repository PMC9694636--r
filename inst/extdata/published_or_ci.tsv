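target	outcome	stratum	or	ci_low	ci_high
t1	GHD	top 25% vs bottom 50%	3.18	2.89	3.51
t2	GHD	top 10% vs bottom 50%	4.84	4.28	5.46
t3	GHD	top 5% vs bottom 50%	6.19	5.30	7.24
t4	GHD	top 2% vs bottom 50%	9.25	7.35	11.64
t5	GHD	top 1% vs bottom 50%	11.18	8.11	15.41
t6	preeclampsia	top 10% vs bottom 50%	5.67	4.98	6.45
t7	preeclampsia	top 5% vs bottom 50%	7.84	6.66	9.23
t8	preeclampsia	top 1% vs bottom 50%	12.76	9.19	17.71
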