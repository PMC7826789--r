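name	smarts	priority	is_fallback
4-anilino-quinazoline	c1ccc(cc1)Nc1ncnc2ccccc12	1	0
quinazoline	c1ncc2ccccc2n1	2	0
quinoline	c1ccc2ncccc2c1	3	0
indazole	c1ccc2[nH]ncc2c1	4	0
oxindole	O=C1Cc2ccccc2N1	5	0
2-aminopyrimidine	Nc1ncccn1	6	0
indole	c1ccc2[nH]ccc2c1	7	0
pyrazole	c1cc[nH]n1	8	0
pyrimidine	c1cncnc1	9	0
imidazole	c1c[nH]cn1	10	0
pyridine	c1ccncc1	11	0
other		99	1
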