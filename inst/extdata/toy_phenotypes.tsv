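subject_id	afp	ca199	cea	age	sex	bmi	smoking	drinking	physical_activity	family_history	event	followup_time	cancer_site
P1	2.74	8.82	2.18	65.2	male	24.0	ever	never	yes	no	1	2.5	stomach
P2	0.003	7.79	1.79	62.1	female	24.3	never	never	yes	no	0	5	none
P3	3.91	14.73	2.74	58.8	male	25.1	ever	ever	no	yes	0	5	none
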