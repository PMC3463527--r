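cohort	tp	fn	tn	fp
training	58	2	55	5
verification	17	2	19	1
validation	34	4	55	7
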