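source_code,target
135446,N06D
6719,N06D
29046,C09A
6918,C07A
83367,C10A
36567,C10A
6809,A10B
11289,B01A
1364430,B01A
36437,N06A
321988,N06A
6470,N05B
7646,A02B
40790,A02B
5640,M01A
7258,M01A
161,N02B
4603,C03C
10582,H03A
435,R03A
51272,N05A
25480,N03A
17767,C08C
77492,G04C
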