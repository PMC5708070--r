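exposure,sex,p
sexual_violence,total,0.072
sexual_violence,male,0.061
sexual_violence,female,0.085
physical_violence,total,0.261
physical_violence,male,0.240
physical_violence,female,0.287
emotional_violence,total,0.126
emotional_violence,male,0.097
emotional_violence,female,0.162
neglect,total,0.122
neglect,male,0.098
neglect,female,0.151
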