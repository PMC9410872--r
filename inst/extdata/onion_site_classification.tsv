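chromosome	anchored_polymorphisms	anchored_unigenes	anchored_markers	chromosome_only_polymorphisms	chromosome_only_unigenes	chromosome_only_markers
1	162	35	31	205	66	20
2	285	50	40	395	91	30
3	138	30	25	222	48	37
4	99	19	19	392	66	42
5	169	22	20	393	68	42
6	156	32	31	156	38	29
7	148	25	21	259	59	41
8	154	24	22	355	61	30
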