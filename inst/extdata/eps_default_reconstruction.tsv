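class	hydrophilic	acceptor	donor	hydrophobic	aromatic	neutral	neutral_donor	neutral_acceptor
hydrophilic	2	2	2	0.5	1	1	2	2
acceptor	2	0.5	2	0.5	1	1	2	0.5
donor	2	2	0.5	0.5	1	1	0.5	2
hydrophobic	0.5	0.5	0.5	2	2	1	0.5	0.5
aromatic	1	1	1	2	2	1	1	1
neutral	1	1	1	1	1	1	1	1
neutral_donor	2	2	0.5	0.5	1	1	0.5	2
neutral_acceptor	2	0.5	2	0.5	1	1	2	0.5
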