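construct_id,mw_rh_kda,mw_sls_kda,mw_sls_sd_kda,mw_th_kda
APP-E1,29,22.9,0.2,21.7
APP-E1_ED,46,23.4,2.5,25.6
APP-E1_ED_AcD,88,33.6,1.9,32.3
APP-E2,27,27.0,0.3,25.6
APP-E2_JMR,75,40.6,0.5,40.1
APP-Ecto,178,72.2,5.8,69.1
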