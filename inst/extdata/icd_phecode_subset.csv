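source_code,target
331.83,292.2
294.9,290.9
G31.84,292.2
F06.7,292.2
F09,290.9
R41.840,292.4
R41.841,292.4
R41.89,292.4
R41.9,292.4
331.0,290.11
G30,290.11
G30.0,290.11
G30.1,290.11
G30.8,290.11
G30.9,290.11
I10,401.1
E78.5,272.1
E78.0,272.11
E11.9,250.2
E11.65,250.2
I48.91,427.21
I25.10,411.4
I50.9,428.2
I63.9,433.21
I67.2,433.1
N39.0,591
N18.3,585.3
N40.0,600
M54.5,760
M17.9,740.1
M19.90,740.9
M81.0,743.1
M25.50,745
K21.9,530.11
K59.00,563
K92.2,578.8
F32.9,296.22
F41.9,300.1
F03.90,290.1
G47.00,327.4
G20,332
G40.909,345
D64.9,285
J44.9,496
J45.909,495
E03.9,244.4
E66.9,278.1
E55.9,261.4
H25.9,366
H40.9,365
H91.90,389.9
R53.83,798
R42,386.9
R55,418.1
R51,339
Z87.891,318
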