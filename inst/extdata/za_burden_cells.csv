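exposure,outcome,daly_loss,value_million
sexual_violence,depression,14127,1032
sexual_violence,anxiety,7941,580
sexual_violence,alcohol_abuse,70520,5152
sexual_violence,drug_abuse,18122,1324
sexual_violence,stds,1106,81
sexual_violence,hiv,181841,13285
sexual_violence,interpersonal_violence,36764,2686
sexual_violence,self_harm,44677,3264
physical_violence,serious_mental_illness,90597,6619
physical_violence,anxiety,18236,1332
physical_violence,alcohol_abuse,119261,8713
physical_violence,drug_abuse,14041,1026
physical_violence,hiv,816045,59621
physical_violence,interpersonal_violence,45403,3317
physical_violence,self_harm,86984,6355
emotional_violence,serious_mental_illness,42824,3129
emotional_violence,anxiety,13767,1006
emotional_violence,alcohol_abuse,40128,2932
emotional_violence,drug_abuse,6434,470
emotional_violence,hiv,458238,33479
emotional_violence,interpersonal_violence,33290,2432
emotional_violence,self_harm,55520,4056
neglect,depression,48008,3507
neglect,anxiety,11515,841
neglect,alcohol_abuse,29717,2171
neglect,drug_abuse,3604,263
neglect,stds,960,70
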