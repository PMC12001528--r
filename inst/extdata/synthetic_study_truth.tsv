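subject_id	condition	magnitude	halflife
subj_01	wheel	4.30566771	6.04511539
subj_01	atv	6.65827892	11.0011711
subj_02	wheel	11.8074173	13.2094274
subj_02	atv	5.1275922	15.0429734
subj_03	wheel	0.613088902	9.52921664
subj_03	atv	13.056705	8.30518786
subj_04	wheel	4.86345238	11.8853697
subj_04	atv	0.766804673	13.8326264
subj_05	wheel	9.03812504	11.5834979
subj_05	atv	4.44651229	13.6446445
subj_06	wheel	1.06470333	12.3501298
subj_06	atv	8.50832967	14.1713712
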