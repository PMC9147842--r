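# Activation-pathway microswitch pairs with expected direction of contact
# change upon agonist binding.
3.40	6.48	increase
2.50	3.39	increase
7.50	7.55	increase
1.49	7.50	increase
3.49	3.50	decrease
1.53	7.53	decrease
3.46	6.37	decrease
3.43	6.43	decrease
2.43	7.53	decrease
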