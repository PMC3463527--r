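stage	cohort	detected	total
I	training	6	7
I	verification	0	1
I	validation	4	5
II	training	10	10
II	verification	4	4
II	validation	11	13
III	training	29	30
III	verification	8	9
III	validation	10	10
IV	training	13	13
IV	verification	4	4
IV	validation	8	9
UNKNOWN	training	0	0
UNKNOWN	verification	1	1
UNKNOWN	validation	1	1
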