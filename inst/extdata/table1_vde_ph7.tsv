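chain	residue_name	residue_number	pKa	std
A	ASP	86	5.0	0.1
A	ASP	98	5.3	0.2
A	ASP	117	5.3	0.3
A	HIS	168	7.0	0.3
A	ASP	206	5.2	0.1
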