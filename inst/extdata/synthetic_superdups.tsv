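585	chr1	1e+05	105000	chr2:5e+05	1000	+	chr2	5e+05	505000	2e+08	65570	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	5000	5	120	5000	4855	145	300	150	0.971	0.969	0.05	0.05
585	chr1	103000	110000	chr3:8e+05	1000	+	chr3	8e+05	807000	2e+08	66457	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	7000	5	120	7000	6664	336	300	150	0.952	0.95	0.05	0.05
585	chr2	5e+05	505000	chr3:8e+05	1000	+	chr3	8e+05	805000	2e+08	19004	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	5000	5	120	5000	4705	295	300	150	0.941	0.939	0.05	0.05
585	chr4	2e+05	202000	chr4:9e+05	1000	+	chr4	9e+05	902000	2e+08	73612	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	2000	5	120	2000	1990	10	300	150	0.995	0.993	0.05	0.05
585	chr5	1e+06	1010000	chr6:1e+06	1000	+	chr6	1e+06	1010000	2e+08	28886	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	10000	5	120	10000	9120	880	300	150	0.912	0.91	0.05	0.05
585	chrX	3e+05	305000	chr7:4e+05	1000	+	chr7	4e+05	405000	2e+08	37598	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	5000	5	120	5000	4830	170	300	150	0.966	0.964	0.05	0.05
585	chr7	6e+05	608000	chrY:1e+05	1000	+	chrY	1e+05	108000	2e+08	21667	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	8000	5	120	8000	7464	536	300	150	0.933	0.931	0.05	0.05
585	chr8	50000	50900	chr9:70000	1000	+	chr9	70000	70900	2e+08	31467	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	900	5	120	900	882	18	300	150	0.98	0.978	0.05	0.05
585	chr8	150000	155000	chr9:170000	1000	+	chr9	170000	175000	2e+08	44589	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	5000	5	120	5000	4975	25	300	150	0.995	0.993	0.05	0.05
585	chr10	250000	260000	chr10:262000	1000	+	chr10	262000	272000	2e+08	88497	100	N/A	N/A	N/A	N/A	align_both/0000/both0.psl	10000	5	120	10000	9610	390	300	150	0.961	0.959	0.05	0.05
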