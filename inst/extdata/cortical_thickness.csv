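group,mean_thickness_um,sd_um,duration_days
sedentary,957,110,56
continuous,708,65,56
intermittent,1024,112,56
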