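@RELATION toy_dag

@ATTRIBUTE f1 numeric
@ATTRIBUTE f2 numeric
@ATTRIBUTE f3 numeric
@ATTRIBUTE class hierarchical GO:A,GO:B,GO:C/GO:A,GO:C/GO:B,GO:D/GO:C

@DATA
1,2,3,GO:D
0,?,1,GO:C
?,?,?,GO:A@GO:B
2,2,2,?
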