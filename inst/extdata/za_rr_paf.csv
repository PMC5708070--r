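exposure,outcome,sex,rr,paf_printed
sexual_violence,anxiety,total,1.83,0.06
sexual_violence,drug_abuse,total,3.23,0.14
sexual_violence,stds,total,1.4,0.03
sexual_violence,self_harm,total,2.84,0.12
sexual_violence,alcohol_abuse,male,2.2,0.07
sexual_violence,interpersonal_violence,male,1.5,0.0296
sexual_violence,depression,female,1.73,0.06
sexual_violence,alcohol_abuse,female,2.25,0.1
sexual_violence,stds,female,2,0.08
sexual_violence,hiv,female,1.6,0.05
sexual_violence,interpersonal_violence,female,1.94,0.074
physical_violence,serious_mental_illness,total,1.41,0.1
physical_violence,anxiety,total,1.57,0.13
physical_violence,alcohol_abuse,total,1.55,0.13
physical_violence,drug_abuse,total,1.46,0.11
physical_violence,interpersonal_violence,total,1.18,0.0449
physical_violence,self_harm,total,2.13,0.23
physical_violence,interpersonal_violence,male,1.35,0.0775
physical_violence,hiv,female,1.97,0.22
physical_violence,interpersonal_violence,female,1.48,0.1211
emotional_violence,serious_mental_illness,total,1.38,0.05
emotional_violence,anxiety,total,1.86,0.1
emotional_violence,alcohol_abuse,total,1.35,0.04
emotional_violence,drug_abuse,total,1.41,0.05
emotional_violence,interpersonal_violence,total,1.27,0.0329
emotional_violence,self_harm,total,2.35,0.15
emotional_violence,alcohol_abuse,male,1.33,0.03
emotional_violence,hiv,female,1.86,0.12
neglect,anxiety,total,1.73,0.08
neglect,depression,male,2.9,0.16
neglect,drug_abuse,male,1.45,0.04
neglect,depression,female,1.66,0.09
neglect,alcohol_abuse,female,2.12,0.14
neglect,stds,female,1.39,0.06
witnessing_family_violence,anxiety,total,1.59,0.13
witnessing_family_violence,interpersonal_violence,male,1.86,0.1591
witnessing_family_violence,interpersonal_violence,female,1.71,0.1648
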