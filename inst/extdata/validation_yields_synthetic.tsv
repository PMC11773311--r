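overhang	yield_pct	sd_pct	n
UUCG	68.0	3.1	3
UGCG	64.0	2.8	3
UCCG	60.0	3.4	3
UACG	56.0	2.5	3
CAAG	38.0	2.2	3
CGCG	34.0	1.9	3
CUAG	31.0	2.4	3
CCUG	29.0	1.7	3
CAGG	26.0	2.0	3
CUCG	22.0	1.5	3
GAAA	35.0	2.1	3
GUGA	31.0	1.8	3
GCAA	29.0	2.3	3
GGGA	27.0	1.6	3
GACA	25.0	1.9	3
GUUA	21.0	1.4	3
UACC	26.0	1.8	3
UGAC	22.0	1.6	3
UCUC	18.0	1.2	3
UUAC	14.0	1.1	3
UUCA	12.0	1.0	3
GUUG	15.0	1.3	3
UGGU	9.0	0.8	3
CUUU	7.0	0.7	3
AACA	5.0	0.6	3
ACGA	4.0	0.5	3
AAAC	0.30	0.05	3
AGGU	0.25	0.04	3
GAAU	0.22	0.04	3
AUCC	0.20	0.03	3
GGAU	0.18	0.03	3
ACAC	0.15	0.03	3
GUGU	0.12	0.02	3
AAGC	0.18	0.03	3
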