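sample_id	subject_id	condition	time_h	is_baseline
subj_01_wheel_t0	subj_01	wheel	0	TRUE
subj_01_wheel_t0.5	subj_01	wheel	0.5	FALSE
subj_01_wheel_t3	subj_01	wheel	3	FALSE
subj_01_wheel_t6	subj_01	wheel	6	FALSE
subj_01_wheel_t24	subj_01	wheel	24	FALSE
subj_01_wheel_t48	subj_01	wheel	48	FALSE
subj_01_atv_t0	subj_01	atv	0	TRUE
subj_01_atv_t0.5	subj_01	atv	0.5	FALSE
subj_01_atv_t3	subj_01	atv	3	FALSE
subj_01_atv_t6	subj_01	atv	6	FALSE
subj_01_atv_t24	subj_01	atv	24	FALSE
subj_01_atv_t48	subj_01	atv	48	FALSE
subj_02_wheel_t0	subj_02	wheel	0	TRUE
subj_02_wheel_t0.5	subj_02	wheel	0.5	FALSE
subj_02_wheel_t3	subj_02	wheel	3	FALSE
subj_02_wheel_t6	subj_02	wheel	6	FALSE
subj_02_wheel_t24	subj_02	wheel	24	FALSE
subj_02_wheel_t48	subj_02	wheel	48	FALSE
subj_02_atv_t0	subj_02	atv	0	TRUE
subj_02_atv_t0.5	subj_02	atv	0.5	FALSE
subj_02_atv_t3	subj_02	atv	3	FALSE
subj_02_atv_t6	subj_02	atv	6	FALSE
subj_02_atv_t24	subj_02	atv	24	FALSE
subj_02_atv_t48	subj_02	atv	48	FALSE
subj_03_wheel_t0	subj_03	wheel	0	TRUE
subj_03_wheel_t0.5	subj_03	wheel	0.5	FALSE
subj_03_wheel_t3	subj_03	wheel	3	FALSE
subj_03_wheel_t6	subj_03	wheel	6	FALSE
subj_03_wheel_t24	subj_03	wheel	24	FALSE
subj_03_wheel_t48	subj_03	wheel	48	FALSE
subj_03_atv_t0	subj_03	atv	0	TRUE
subj_03_atv_t0.5	subj_03	atv	0.5	FALSE
subj_03_atv_t3	subj_03	atv	3	FALSE
subj_03_atv_t6	subj_03	atv	6	FALSE
subj_03_atv_t24	subj_03	atv	24	FALSE
subj_03_atv_t48	subj_03	atv	48	FALSE
subj_04_wheel_t0	subj_04	wheel	0	TRUE
subj_04_wheel_t0.5	subj_04	wheel	0.5	FALSE
subj_04_wheel_t3	subj_04	wheel	3	FALSE
subj_04_wheel_t6	subj_04	wheel	6	FALSE
subj_04_wheel_t24	subj_04	wheel	24	FALSE
subj_04_wheel_t48	subj_04	wheel	48	FALSE
subj_04_atv_t0	subj_04	atv	0	TRUE
subj_04_atv_t0.5	subj_04	atv	0.5	FALSE
subj_04_atv_t3	subj_04	atv	3	FALSE
subj_04_atv_t6	subj_04	atv	6	FALSE
subj_04_atv_t24	subj_04	atv	24	FALSE
subj_04_atv_t48	subj_04	atv	48	FALSE
subj_05_wheel_t0	subj_05	wheel	0	TRUE
subj_05_wheel_t0.5	subj_05	wheel	0.5	FALSE
subj_05_wheel_t3	subj_05	wheel	3	FALSE
subj_05_wheel_t6	subj_05	wheel	6	FALSE
subj_05_wheel_t24	subj_05	wheel	24	FALSE
subj_05_wheel_t48	subj_05	wheel	48	FALSE
subj_05_atv_t0	subj_05	atv	0	TRUE
subj_05_atv_t0.5	subj_05	atv	0.5	FALSE
subj_05_atv_t3	subj_05	atv	3	FALSE
subj_05_atv_t6	subj_05	atv	6	FALSE
subj_05_atv_t24	subj_05	atv	24	FALSE
subj_05_atv_t48	subj_05	atv	48	FALSE
subj_06_wheel_t0	subj_06	wheel	0	TRUE
subj_06_wheel_t0.5	subj_06	wheel	0.5	FALSE
subj_06_wheel_t3	subj_06	wheel	3	FALSE
subj_06_wheel_t6	subj_06	wheel	6	FALSE
subj_06_wheel_t24	subj_06	wheel	24	FALSE
subj_06_wheel_t48	subj_06	wheel	48	FALSE
subj_06_atv_t0	subj_06	atv	0	TRUE
subj_06_atv_t0.5	subj_06	atv	0.5	FALSE
subj_06_atv_t3	subj_06	atv	3	FALSE
subj_06_atv_t6	subj_06	atv	6	FALSE
subj_06_atv_t24	subj_06	atv	24	FALSE
subj_06_atv_t48	subj_06	atv	48	FALSE
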