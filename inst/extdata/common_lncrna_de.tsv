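dry_region	dry_fpkm	lact_region	lact_fpkm	p_value
chr1:88402354-88403436	0.552	chr1:88402258-88403346	0.436	0.2258
chr10:28036993-28037708	7.006	chr10:28036875-28037846	4.436	<2.20e-16
chr11:102644124-102648416	0.592	chr11:102644428-102648357	0.374	4.48e-11
chr11:74657704-74660914	0.325	chr11:74658354-74660959	0.281	0.06305
chr12:32163152-32163433	0.953	chr12:32163199-32163464	0.966	0.8596
chr12:84995822-84996199	19.591	chr12:84995788-84996023	16.090	0.03071
chr13:29201242-29205645	0.305	chr13:29202525-29205728	0.554	1.80e-10
chr13:63992771-63994410	0.750	chr13:63992252-63994789	0.310	1.01e-7
chr13:76610578-76612313	0.617	chr13:76610635-76611936	0.562	0.4465
chr14:17032-17554	0.585	chr14:16830-18164	0.733	0.001775
chr16:42802614-42812241	33.971	chr16:42802637-42812194	15.692	<2.20e-16
chr16:48586547-48586896	0.458	chr16:48584486-48586868	0.612	0.0005258
chr16:71804283-71805220	1.440	chr16:71804288-71805212	18.671	<2.20e-16
chr17:69703586-69705950	2.227	chr17:69703579-69705885	1.975	0.3815
chr18:13007057-13010244	5.469	chr18:13007179-13009811	28.722	6.78e-13
chr18:1829126-1830665	0.196	chr18:1829460-1830200	0.398	0.0001832
chr18:38105619-38111753	6.826	chr18:38105601-38111755	3.175	<2.20e-16
chr18:58480168-58480492	0.326	chr18:58479948-58480580	0.448	0.0004047
chr18:7018326-7020326	0.521	chr18:7018199-7020326	0.283	2.41e-08
chr19:41517108-41519655	0.550	chr19:41518998-41519227	0.288	1.28e-14
chr2:111874235-111875148	4.087	chr2:111874066-111877333	2.759	1.96e-5
chr2:115539609-115540162	235.756	chr2:115539562-115540164	138.488	7.90e-10
chr2:125783114-125794043	24.285	chr2:125777445-125793948	33.604	3.36e-9
chr21:58272796-58274409	1.584	chr21:58272808-58274430	0.854	<2.20e-16
chr21:68475571-68478473	2.627	chr21:68475747-68477894	2.432	0.6144
chr23:11415564-11420435	19.060	chr23:11415556-11420435	8.688	<2.20e-16
chr23:17153445-17154227	8.728	chr23:17153446-17154226	10.971	0.0002695
chr23:17771969-17776464	2.292	chr23:17771923-17776476	0.578	<2.20e-16
chr25:1035522-1036687	10.186	chr25:1035522-1036586	16.318	5.80e-15
chr25:35533291-35534130	0.988	chr25:35533317-35534096	19.412	<2.20e-16
chr25:39512349-39513122	12.600	chr25:39512418-39513043	5.562	<2.20e-16
chr25:488853-489320	3.302	chr25:488852-489379	2.741	0.02195
chr25:786947-787788	1.176	chr25:786326-788530	0.780	3.55e-8
chr26:10508859-10510408	0.425	chr26:10508507-10510415	0.526	2.61e-5
chr26:21485237-21487166	0.418	chr26:21485168-21487115	1.136	2.49e-11
chr26:51014183-51020151	0.424	chr26:51016793-51020761	0.234	1.81e-14
chr27:1092242-1093287	0.894	chr27:1092247-1093275	1.036	0.08457
chr29:46399007-46401176	0.316	chr29:46399026-46401485	0.302	0.745
chr29:46623288-46624946	1.844	chr29:46623270-46625478	3.484	1.86e-9
chr29:47279192-47281419	0.440	chr29:47278057-47281321	1.610	<2.20e-16
chr29:47437521-47440208	0.603	chr29:47437552-47440146	1.012	3.96e-12
chr4:52093644-52094267	4.437	chr4:52093643-52094277	0.438	1.16e-14
chr5:118095776-118100684	0.434	chr5:118095874-118100834	0.303	9.99e-5
chr6:3400389-3401869	0.596	chr6:3400394-3401718	5.301	<2.20e-16
chr6:62052709-62053912	0.368	chr6:62052696-62054059	0.511	0.002736
chr7:10013140-10014516	1.509	chr7:10013140-10014265	0.391	2.82e-8
chr7:11559071-11560742	0.058	chr7:11559861-11561374	0.100	0.2047
chr7:17181130-17183216	0.703	chr7:17181196-17183208	11.387	<2.20e-16
chr7:60229378-60232948	9.270	chr7:60229471-60232796	4.910	7.91e-15
chr9:98186197-98187338	1.152	chr9:98186218-98187339	3.450	<2.20e-16
ChrUn.004.1159:35363-37180	0.171	ChrUn.004.1159:35361-38038	0.344	3.20e-5
ChrUn.004.301:120666-127066	0.410	ChrUn.004.301:124684-128068	0.170	6.17e-15
ChrUn.004.3283:1785-2847	0.330	ChrUn.004.3283:1822-2792	2.147	8.56e-13
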