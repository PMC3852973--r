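id	parent	ref_start	ref_end	init_met	ctag
APP-Ecto	P05067-4	18	624	TRUE	HHHHHH
APP-E1_ED_AcD	P05067-4	18	288	TRUE	HHHHHH
APP-E2_JMR	P05067-4	295	624	TRUE	HHHHHH
APP-E1_ED	P05067-4	18	227	TRUE	HHHHHH
APP-E1	P05067-4	18	190	TRUE	HHHHHH
APP-E2	P05067-4	295	500	TRUE	HHHHHH
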