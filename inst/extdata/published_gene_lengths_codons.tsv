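gene	Lolium_perenne	Lolium_multiflorum	Festuca_pratensis	Festuca_arundinacea	Festuca_altissima	Festuca_ovina	size_difference
atpA	508	508	508	508	508	505	3
atpI	248	248	248	248	248	247	1
cemA	231	231	231	231	231	226	5
clpI	217	217	217	215	217	215	2
infA	108	108	108	114	114	114	6
ndhD	503	503	503	501	501	501	2
ndhF	742	742	742	739	740	740	3
ndhH	60	60	60	60	63	67	7
psbF	40	40	40	40	43	40	3
rbcL	478	478	478	488	478	480	10
rpl32	60	60	60	68	60	64	8
rpoC2	1467	1467	1474	1505	1474	1474	38
rps15	91	91	91	91	93	91	2
rps16	90	93	90	89	86	86	7
rps18	157	157	157	150	157	171	21
ycf68	NA	127	127	127	145	145	18
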