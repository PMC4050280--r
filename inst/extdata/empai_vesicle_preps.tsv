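protein	accession	mass_da	empai_aff1	printed_pct_aff1	empai_eff1	printed_pct_eff1
Protein AFF-1 anchor cell fusion failure-1	gi|193204255	68617	2.07	33	NA	NA
Protein EFF-1 isoform a	gi|71982882	75494	NA	NA	1.66	16
Histone H2B homologue	gi|156371481	24545	1.78	28	1.78	17
Histone cluster 1 H2ag-like	gi|291410763	27347	NA	NA	1	10
Actin family	gi|178045	26147	1.05	17	0.35	3
Hemoglobin fetal subunit beta	gi|62460494	15963	0.78	12	1.62	15
Serum albumin	gi|1351907	71244	0.2	3	0.31	3
Galectin-3-binding protein	gi|81861611	65270	0.41	7	0.63	6
60S acidic ribosomal protein P2	gi|133062	4692	NA	NA	0.79	8
40S ribosomal protein SA-like	gi|296190805	32906	NA	NA	0.47	4
Guanine nucleotide-binding protein subunit beta-2-like 1	gi|5174447	35511	NA	NA	0.56	5
Glyceraldehyde-3-phosphate dehydrogenase-like	gi|488563203	35942	NA	NA	0.55	5
Laminin-binding protein	gi|34234	31888	NA	NA	0.49	5
Tubulin beta-3 chain	gi|12963615	50842	NA	NA	0.37	3
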