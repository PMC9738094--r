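# Published pan-cancer composite-score table (worked example): cancer types
# with the six BRCAness features normalized against the breast (ref1) and
# ovarian (ref2) reference cohorts, plus the published Sum. "-" = feature
# unavailable for that cancer type (e.g. fewer than 5 normal samples for the
# expression feature). The final row is the reference itself (all 1.0).
cancer_type	somatic_ref1	germline_ref1	homozygotic_ref1	methylation_ref1	expression_ref1	prognosis_ref1	somatic_ref2	germline_ref2	homozygotic_ref2	methylation_ref2	expression_ref2	prognosis_ref2	sum_published
UCEC	5.9	4.7	0.7	1.0	7.0	3.0	11.0	17.2	0.5	1.0	7.0	3.0	62.1
BLCA	3.8	2.0	1.3	1.0	10.5	1.0	4.8	14.6	1.0	1.0	10.5	1.0	52.6
PAAD	1.5	1.9	0.2	1.0	5.5	9.0	4.5	6.1	0.1	1.0	5.5	9.0	45.3
LGG	1.5	1.9	0.7	1.0	-	12.0	4.6	5.7	0.5	1.1	-	12.0	41.0
SARC	1.1	1.2	1.8	1.0	8.5	4.5	2.9	4.0	1.4	1.0	8.5	4.5	40.5
LUAD	1.8	1.5	1.0	1.0	0.0	7.0	3.5	6.9	0.8	1.0	0.0	7.0	31.6
KICH	1.2	1.2	0.1	1.0	3.0	6.5	2.9	4.2	0.1	1.0	3.0	6.5	30.5
UCS	3.2	4.0	0.7	0.9	-	0.0	9.6	10.1	0.5	0.9	-	0.0	30.0
ACC	0.4	0.7	0.8	1.0	-	10.0	1.6	1.4	0.6	1.0	-	10.0	27.4
COAD	2.9	2.2	0.7	1.0	0.0	1.0	5.3	11.0	0.6	1.0	0.0	1.0	26.8
LIHC	1.1	0.8	0.7	1.0	0.5	7.0	1.8	4.4	0.6	1.0	0.5	7.0	26.4
ESCA	2.0	3.3	1.0	1.0	1.0	0.0	7.7	7.7	0.8	1.0	1.0	0.0	26.4
HNSC	2.5	2.4	0.7	1.0	0.5	1.0	5.8	9.5	0.5	1.0	0.5	1.0	26.4
READ	2.3	2.4	0.5	1.0	2.0	0.0	5.8	8.5	0.4	1.0	2.0	0.0	25.9
STAD	2.8	2.6	1.0	1.0	0.0	0.0	6.0	10.5	0.8	1.0	0.0	0.0	25.6
SKCM	2.5	0.8	1.1	1.0	-	3.5	1.9	9.3	0.9	1.0	-	3.5	25.5
LUSC	2.7	2.6	1.1	1.0	0.0	0.0	6.3	9.9	0.8	1.0	0.0	0.0	25.3
MESO	0.7	0.8	1.2	1.0	-	7.0	1.9	2.4	0.9	1.0	-	7.0	23.9
KIRC	0.5	0.3	1.0	1.0	0.5	7.0	0.8	1.8	0.8	1.0	0.5	7.0	22.3
KIRP	0.4	0.1	0.5	1.0	0.0	7.5	0.3	1.5	0.4	1.1	0.0	7.5	20.3
PRAD	0.5	0.5	3.1	1.0	1.0	3.0	1.1	2.0	2.4	1.0	1.0	3.0	19.6
BRCA&OV	1.0	1.0	1.0	1.0	1.0	1.0	1.0	1.0	1.0	1.0	1.0	1.0	12.0
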