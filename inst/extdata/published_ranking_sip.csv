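rank,item_id,sfi,criterion
1,SCI-57,3972,B1
2,SCI-11,3260,B2
3,SCI-41,2914,B1
4,SCI-7,2678,B1
5,SCI-48,2655,B1
6,SCI-4,2224,A
7,SCI-12,1833,A
8,SCI-1,1749,B3
9,SCI-14,1638,B2
10,SCI-38,1609,B1
11,SCI-61,1601,B3
12,SCI-34,1464,B2
13,SCI-47,1398,B2
14,SCI-35,1217,A
15,SCI-24,1142,B2
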