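case_id	breed	sex	bw_kg	ga_days
1	Red Danish x Holstein	Female	7.3	272
2	Holstein	Female	30.5	278
3	Holstein	Male	32.0	277
4	Holstein	Male	NR	280
5	Holstein	Male	NR	285
6	Holstein	Male	32.7	272
7	Holstein	Female	27.4	283
8	Holstein	Male	37.3	NR
9	Holstein	Male	NR	296
10	Holstein	Female	30.0	288
11	Holstein	Male	27.1	266
12	Holstein	Male	32.5	276
13	Holstein	Male	26.0	295
14	Holstein	Male	NR	278
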