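tx_id	chrom	strand	exons	rpkm_overall	rpkm_reps	designed_fate
NOVEL001	chrS	-	1046758-1047158,1048258-1048658	3.5784	1.9855,0.3129,0.7388	pass
NOVEL002	chrS	+	1076758-1077158,1078258-1078658	3.5576	1.73,1.769,1.9639	pass
NOVEL003	chrS	-	1106758-1107158,1108258-1108658	0.8742	1.9377,0.5739,2.4809	pass
NOVEL004	chrS	-	1136758-1137158,1138258-1138658	0.1358	0.3311,0.1973,0.3173	expression
NOVEL005	chrS	+	1166758-1167158,1168258-1168658	2.1277	0.8753,1.7255,2.5064	pass
NOVEL006	chrS	+	1196758-1197158,1198258-1198658	3.9585	2.3524,2.207,1.8971	pass
NOVEL007	chrS	+	1226758-1227158,1228258-1228658	0.8407	1.613,2.604,1.5741	pass
NOVEL008	chrS	-	1256758-1257458	3.7525	0.429,2.2046,1.7296	structure
NOVEL009	chrS	-	1286758-1287458	3.9158	0.4058,0.4381,1.8655	structure
NOVEL010	chrS	-	1316758-1317458	4.2659	2.0771,0.9654,1.3606	structure
NOVEL011	chrS	-	447473-447873,448973-449373	1.5222	1.4475,2.8909,1.778	distance
NOVEL012	chrS	-	1346758-1347158,1348258-1348658	3.9488	0.8997,1.3539,1.4151	pass
NOVEL013	chrS	-	1376758-1377158,1378258-1378658	2.9767	0.9496,2.9196,1.6364	pass
NOVEL014	chrS	+	1406758-1407158,1408258-1408658	1.903	1.6155,1.5047,2.6468	pass
NOVEL015	chrS	-	121612-122012,123112-123512	4.4171	1.5193,0.5324,0.9328	distance
NOVEL016	chrS	-	898930-899330,900430-900830	4.0691	1.1911,0.9892,2.488	distance
NOVEL017	chrS	+	1436758-1437158,1438258-1438658	3.3412	2.0247,2.7279,2.9611	pass
NOVEL018	chrS	-	1466758-1467458	4.3629	1.6762,0.7652,2.8199	structure
NOVEL019	chrS	+	1496758-1497158,1498258-1498658	1.2759	2.7176,1.1686,0.9185	pass
NOVEL020	chrS	-	1526758-1527158,1528258-1528658	0.199	0.4804,0.0483,0.5781	expression
NOVEL021	chrS	+	601197-601597,602697-603097	1.4621	1.7965,2.9386,1.492	distance
NOVEL022	chrS	+	1556758-1557158,1558258-1558658	0.3302	0.4412,0.0114,0.414	expression
NOVEL023	chrS	+	1586758-1586958,1587758-1588008	4.9114	2.9505,2.2,2.2535	structure
NOVEL024	chrS	+	1616758-1617158,1618258-1618658	2.1498	0.5389,0.4302,1.5667	pass
NOVEL025	chrS	-	1646758-1647158,1648258-1648658	0.1923	0.3108,0.0334,0.2619	expression
NOVEL026	chrS	+	1676758-1677158,1678258-1678658	2.8748	1.4006,2.473,2.037	pass
NOVEL027	chrS	-	1706758-1707458	4.2996	0.4454,1.4059,1.5721	structure
NOVEL028	chrS	+	1736758-1737158,1738258-1738658	0.3494	0.5407,0.0295,0.4761	expression
NOVEL029	chrS	-	1766758-1766958,1767758-1768008	2.36	1.23,1.2368,0.927	structure
NOVEL030	chrS	+	1796758-1797158,1798258-1798658	2.9349	0.3762,2.7193,0.345	pass
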