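outcome_id	exposure_id	method	or	ci_low	ci_high	pvalue
liver_cancer	serum_iron	ivw-random	2.45	0.81	7.45	0.11
liver_cancer	transferrin_saturation	ivw-random	2.11	1.16	3.83	0.01
liver_cancer	log10_ferritin	ivw-random	10.9	2.44	48.6	2.00e-3
liver_cancer	transferrin	ivw-random	0.30	0.17	0.53	2.99e-5
liver_cancer	serum_iron	weighted-median	2.08	0.97	4.47	0.06
liver_cancer	transferrin_saturation	weighted-median	2.14	1.39	3.31	1.00e-3
liver_cancer	log10_ferritin	weighted-median	12.1	3.24	45.2	3.43e-4
liver_cancer	transferrin	weighted-median	0.30	0.17	0.53	3.31e-5
liver_cancer	serum_iron	mr-egger	49.0	5.64	424	4.17e-4
liver_cancer	transferrin_saturation	mr-egger	4.36	1.87	10.1	1.00e-3
liver_cancer	log10_ferritin	mr-egger	46.4	5.47	394	4.38e-4
liver_cancer	transferrin	mr-egger	0.28	0.11	0.70	7.00e-3
brain_cancer	serum_iron	ivw-random	0.69	0.48	1.00	0.05
brain_cancer	transferrin_saturation	ivw-random	0.75	0.59	0.97	0.03
brain_cancer	log10_ferritin	ivw-random	0.41	0.20	0.88	0.02
brain_cancer	transferrin	ivw-random	1.49	1.04	2.14	0.03
brain_cancer	serum_iron	weighted-median	0.65	0.44	0.96	0.03
brain_cancer	transferrin_saturation	weighted-median	0.71	0.53	0.93	0.02
brain_cancer	log10_ferritin	weighted-median	0.37	0.16	0.83	0.02
brain_cancer	transferrin	weighted-median	1.46	1.01	2.13	0.05
brain_cancer	serum_iron	mr-egger	0.35	0.07	1.63	0.18
brain_cancer	transferrin_saturation	mr-egger	0.68	0.36	1.29	0.24
brain_cancer	log10_ferritin	mr-egger	0.36	0.08	1.69	0.19
brain_cancer	transferrin	mr-egger	1.38	0.74	2.57	0.31
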