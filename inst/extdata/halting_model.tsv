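# quantile: 0.94999999999999996
# replicates: 1000
# min_len: 3000
# seed: 42
length	gc	threshold
6000	0.20000000000000001	0.00045912145849763515
12500	0.20000000000000001	0.00045912145849763515
25000	0.20000000000000001	0.00026067804773645951
50000	0.20000000000000001	0.0001412319340781459
100000	0.20000000000000001	6.8828173148419158e-05
200000	0.20000000000000001	3.9322570951971737e-05
400000	0.20000000000000001	2.0682335581621034e-05
800000	0.20000000000000001	1.0164101321646826e-05
6000	0.30000000000000004	0.0004917793445353007
12500	0.30000000000000004	0.00045359467600160905
25000	0.30000000000000004	0.00026266513640837985
50000	0.30000000000000004	0.0001399941520205505
100000	0.30000000000000004	7.1328124126711356e-05
200000	0.30000000000000004	3.7156877216491715e-05
400000	0.30000000000000004	1.9710461000949043e-05
800000	0.30000000000000004	1.0141963872758054e-05
6000	0.40000000000000002	0.00045655579652946606
12500	0.40000000000000002	0.00045655579652946606
25000	0.40000000000000002	0.00026204992260576163
50000	0.40000000000000002	0.00013721335221668352
100000	0.40000000000000002	6.9987856322953389e-05
200000	0.40000000000000002	3.7132063915606148e-05
400000	0.40000000000000002	1.9539077532243487e-05
800000	0.40000000000000002	1.0109800252218557e-05
6000	0.5	0.00045328194160998263
12500	0.5	0.00045328194160998263
25000	0.5	0.00026168193675389357
50000	0.5	0.00013961970739299044
100000	0.5	7.1497183825391985e-05
200000	0.5	3.7275951913692861e-05
400000	0.5	1.9504851029842132e-05
800000	0.5	9.7659177119686046e-06
6000	0.60000000000000009	0.00045975529712938555
12500	0.60000000000000009	0.00041704604598535026
25000	0.60000000000000009	0.00026084023190422459
50000	0.60000000000000009	0.00013641486655916455
100000	0.60000000000000009	7.1631539404692956e-05
200000	0.60000000000000009	3.5892461706421618e-05
400000	0.60000000000000009	1.9871429816051538e-05
800000	0.60000000000000009	1.0005908530984165e-05
6000	0.69999999999999996	0.000484214465636165
12500	0.69999999999999996	0.000484214465636165
25000	0.69999999999999996	0.00025035876294759855
50000	0.69999999999999996	0.00013294183019112865
100000	0.69999999999999996	7.191832060387789e-05
200000	0.69999999999999996	3.7047557887721818e-05
400000	0.69999999999999996	1.9241572838824038e-05
800000	0.69999999999999996	1.0481950761698222e-05
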