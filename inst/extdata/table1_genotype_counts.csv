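snp_id,genotype_class,code,category,cases,controls
rs1801282,C/C,0,I,46,52
rs1801282,C/C,0,II,84,109
rs1801282,C/C,0,III,63,68
rs1801282,C/C,0,IV,51,64
rs1801282,C/G,1,I,5,1
rs1801282,C/G,1,II,10,13
rs1801282,C/G,1,III,4,8
rs1801282,C/G,1,IV,5,7
rs7799039,"A/A,A/G",0,I,40,45
rs7799039,"A/A,A/G",0,II,77,105
rs7799039,"A/A,A/G",0,III,54,69
rs7799039,"A/A,A/G",0,IV,42,62
rs7799039,G/G,1,I,11,8
rs7799039,G/G,1,II,17,17
rs7799039,G/G,1,III,13,7
rs7799039,G/G,1,IV,14,9
rs12535708,"C/C,C/A",0,I,50,50
rs12535708,"C/C,C/A",0,II,83,114
rs12535708,"C/C,C/A",0,III,60,73
rs12535708,"C/C,C/A",0,IV,52,68
rs12535708,A/A,1,I,1,3
rs12535708,A/A,1,II,11,8
rs12535708,A/A,1,III,7,3
rs12535708,A/A,1,IV,4,3
rs822390,T/T,0,I,41,47
rs822390,T/T,0,II,83,114
rs822390,T/T,0,III,58,72
rs822390,T/T,0,IV,45,65
rs822390,T/G,1,I,6,5
rs822390,T/G,1,II,6,4
rs822390,T/G,1,III,6,4
rs822390,T/G,1,IV,2,3
rs822390,G/G,2,I,4,1
rs822390,G/G,2,II,5,4
rs822390,G/G,2,III,3,0
rs822390,G/G,2,IV,9,3
rs182052,A/A,0,I,6,8
rs182052,A/A,0,II,13,26
rs182052,A/A,0,III,7,18
rs182052,A/A,0,IV,11,15
rs182052,A/G,1,I,28,23
rs182052,A/G,1,II,46,62
rs182052,A/G,1,III,30,38
rs182052,A/G,1,IV,25,38
rs182052,G/G,2,I,17,22
rs182052,G/G,2,II,35,34
rs182052,G/G,2,III,30,20
rs182052,G/G,2,IV,20,18
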