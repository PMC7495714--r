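subject_id	group	age	sex	age_of_onset	disease_duration	braak	thal
s1	PSP	74	male	67	7	2	1
s2	CBD	69	female	NA	NA	1	0
s3	control	80	female	NA	NA	NA	NA
s4	PSP	77	male	70	7	3	2
s5	control	83	male	NA	NA	NA	NA
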