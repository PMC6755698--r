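@RELATION toy_tree

@ATTRIBUTE f1 numeric
@ATTRIBUTE f2 numeric
@ATTRIBUTE class hierarchical 1,1/1.2,1/1.2/1.2.3,2,2/2.1

@DATA
0.5,1.25,1.2.3
-1,?,2.1@1.2
?,3,?
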