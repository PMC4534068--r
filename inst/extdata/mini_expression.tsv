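gene	s1	s2	s3	s4
TP53	1.0	2.0	3.0	4.0
BRCA1	5.0	5.5	6.0	6.5
ERBB2	0.1	0.4	0.2	0.3
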