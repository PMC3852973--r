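fragment	construct_id	protease	edman_read	observed_mass_da	persistent
1	APP-Ecto	v8	VVRV	27900	TRUE
2	APP-Ecto	v8	MLEV	23700	TRUE
3	APP-Ecto	v8	AMLN	16000	TRUE
4	APP-Ecto	v8	MLEV	19900	TRUE
5	APP-E2_JMR	trypsin	STPD	25500	TRUE
6	APP-E2_JMR	trypsin	VEAML	15900	TRUE
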