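exposure,daly_loss,value_million
sexual_violence,375097,27405
physical_violence,1172331,85652
emotional_violence,636434,46499
neglect,93804,6853
all,2277666,166409
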