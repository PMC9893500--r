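variable,FW,WS
dmi_kg_d,9.12,10.09
adg_kg_d,0.85,1.23
rumen_mesor_c,39.80,39.68
rumen_amplitude_c,0.24,0.29
rumen_peak_time_h,16.21,18.81
rectal_mesor_c,39.28,38.96
rectal_amplitude_c,0.25,0.30
rectal_peak_time_h,17.45,19.19
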