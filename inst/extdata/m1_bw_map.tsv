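# Ballesteros-Weinstein labels for human M1 muscarinic receptor (chain A,
# author numbering). 1.49 and 2.43 follow from within-helix position offsets
# anchored at 1.53=46 and 2.50=71.
A:42	1.49
A:46	1.53
A:64	2.43
A:71	2.50
A:112	3.39
A:113	3.40
A:116	3.43
A:119	3.46
A:122	3.49
A:123	3.50
A:367	6.37
A:370	6.40
A:371	6.43
A:378	6.48
A:381	6.51
A:415	7.50
A:418	7.53
A:420	7.55
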