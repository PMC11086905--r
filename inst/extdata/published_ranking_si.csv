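rank,item_id,sfi,criterion
1,SCI-12,4000,A
2,SCI-60,4000,B3
3,SCI-59,3999,B3
4,SCI-38,3977,B1
5,SCI-4,3918,A
6,SCI-51,3901,B1
7,SCI-72,3841,B3
8,SCI-57,3306,B1
9,SCI-74,2339,B4
10,SCI-3,1870,B2
11,SCI-41,1807,B1
12,SCI-13,1192,A
13,SCI-54,580,B1
14,SCI-45,534,B2
15,SCI-7,235,B1
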