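stage	n_GG	n_GT	n_TT
birth	297	163	25
wt40	252	123	1
wt110	169	90	0
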