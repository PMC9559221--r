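allele,eplet,abv
A*11:01,19K,0
A*11:01,62QE,1
A*11:01,144KR,0
A*11:02,62QE,1
A*11:02,144KR,0
DRB1*11:03,71E,0
DRB1*11:03,70DA,1
DRB1*11:03,96Y,0
DRB1*11:04,70DA,1
DRB1*11:04,96Y,0
DQB1*03:03,45EV,1
DQB1*03:03,52PQ,0
DQA1*04:01,40GR,1
DQA1*04:01,69T,0
DQA1*04:01,76L,0
DQA1*04:01,129QS,0
DQA1*03:02,129QS,0
B*35:01,65QIA,0
B*35:01,109F,0
B*35:01,193PV,1
B*35:08,65QIA,0
B*35:08,109F,0
A*02:05,43R,0
A*02:05,62GE,1
A*02:05,107W,0
A*02:01,62GE,1
A*02:01,107W,0
A*02:13,62GE,1
A*29:01,62LQ,0
A*29:01,151AHA,1
A*29:02,62LQ,0
A*29:02,151AHA,1
A*29:02,102DV,0
DQA1*02:01,47KHL,1
DQA1*02:01,187T,0
DQA1*05:01,187T,0
DQB1*02:01,45GE,0
DQB1*02:01,74EL,1
B*15:12,156WA,0
B*15:12,163LW,1
B*15:17,163LW,1
B*51:01,56R,0
B*51:01,163LW,1
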