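id	species	exon2	exon3	exon4	exon5	exon10	exon23	exon31	exon32	exon33_coding	tss_truncation	printed_mw_kda	accession	partial
h-v1	human	+	+	+	+	+	-	+	+	utr_only	NA	131.5	NP_002456	FALSE
h-v2	human	+	+	+	+	+	-	-	+	utr_only	NA	129	NP_996555	FALSE
h-v3	human	+	+	-	-	+	+	-	+	utr_only	NA	128	NP_996556	FALSE
h-v4	human	+	+	-	-	+	-	-	+	utr_only	NA	126.5	NP_996557	FALSE
h-v5	human	+	+	-	-	+	+	+	-	coding	NA	131.5	NP_001241647	FALSE
h-v6	human	+	+	-	-	+	-	+	+	utr_only	NA	129	NP_001241648	FALSE
h-v7	human	-	+	-	-	+	-	+	+	utr_only	NA	128	NP_001241649	FALSE
h-v8	human	+	+	-	-	-	-	+	+	utr_only	NA	127	NP_001241650	FALSE
h-v9	human	-	-	-	-	+	-	+	+	utr_only	NA	126	NP_001241651	FALSE
h-v10	human	-	-	+	-	+	-	-	-	coding	NA	128	NP_001241652	FALSE
h-v002	human	+	-	-	-	+	-	+	+	utr_only	NA	127.5	ENSP00000447362	FALSE
h-v012	human	-	-	-	-	+	-	-	+	utr_only	7	115.5	EAW97667.1	FALSE
h-v013	human	+	+	+	-	+	+	-	+	utr_only	NA	129.5	ENSP00000447660	FALSE
h-v202	human	+	+	-	-	+	+	+	+	utr_only	NA	131	EAW97664.1	FALSE
m-v4	mouse	+	+	-	-	+	-	-	+	utr_only	NA	126	NP_780627	FALSE
m-v002	mouse	+	-	-	-	+	-	+	+	utr_only	NA	126.5	NP_001239301	FALSE
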