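participant	group	n_reference	nlpFN_userFN	nlpFN_userTP	nlpTP_userFN	nlpTP_userTP	n_nlp_fp	nlpTN_userFP	nlpFP_userTN	nlpFP_userFP
Expert	expert	151	59	50	23	19	93	25	93	0
Nonexpert 1	nonexpert	151	46	63	11	31	93	16	88	5
Nonexpert 2	nonexpert	151	43	66	11	31	93	37	86	7
Nonexpert 3	nonexpert	151	49	60	13	29	93	24	88	5
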