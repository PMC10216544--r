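# Published per-sample immunogenicity call counts from a TCR-beta CDR3
# study of lung edema fluid (4 ARDS vs 3 non-ARDS samples): number of
# CDR3 sequences with a positive class I pMHC immunogenicity score, total
# unique CDR3 sequences, and the percent positive as printed.
sample_id	positive	total	percent_printed	group
111	515	1560	33.01	ARDS
176	19	56	33.93	ARDS
186	501	1485	33.74	ARDS
251	64	202	31.68	ARDS
158	7	25	28.00	non_ARDS
162	33	118	27.97	non_ARDS
163	51	169	30.18	non_ARDS
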