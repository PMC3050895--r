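sample	total	ssu	lsu	non_rrna
A	57300	11528	43622	2150
B	48150	4524	41888	1738
C	34849	7726	25359	1764
D	19625	6663	11896	1066
E	17891	5585	10948	1358
F	22748	3221	16494	3033
K	69100	12707	52981	3412
L	75059	8024	59935	7100
N	35276	6482	24587	4207
O	29505	6057	21353	2095
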