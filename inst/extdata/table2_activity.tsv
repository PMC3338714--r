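variant	activity_pct_wt	sd
D86A	81	18
D98L	59	5
D117A	40	14
H168A	20	8
D206I	44	8
D98L/D117A	41	10
D98L/D117A/D206I	16	10
D98L/D117A/D206I/H168A	6	3
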