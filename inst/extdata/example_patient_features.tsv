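feature	A	B	C	D
GFP	2.5429	2.6814	2.9412	2.5121
Occ	3.0817	3.3100	3.7209	1.9061
Dur_ms	79.1481	85.1345	92.6626	67.9401
Cov	0.2439	0.2818	0.3448	0.1295
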