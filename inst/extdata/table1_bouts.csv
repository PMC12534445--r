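bout_id,individual_id,age_at_bout,category,subcategory,typicality,atypical_mode
B01,CH,1.2,tool,leaf_grooming,atypical,omission
B02,CH,1.5,tool,leaf_grooming,typical,
B03,CH,2.3,tool,leaf_grooming,typical,
B04,AL,0.5,tool,leaf_grooming,typical,
B05,AM,3,tool,leaf_grooming,typical,
B06,KO,2.1,tool,leaf_grooming,atypical,commission
B07,EL,1.8,tool,leaf_grooming,atypical,commission
B08,GA,7,tool,leaf_grooming,typical,
B09,AL,0.5,tool,leaf_clipping,atypical,commission
B10,EM,3,tool,leaf_napkin,typical,
B11,NA1,6.2,tool,sponge,atypical,commission
B12,NA1,5.8,tool,sponge,typical,
B13,TO,2.5,tool,sponge,typical,
B14,HD,2,tool,sponge,typical,
B15,KO,2.8,tool,sponge,typical,
B16,BB,3.5,tool,sponge,typical,
B17,CL,2.2,tool,sponge,typical,
B18,ZW,3.8,tool,sponge,typical,
B19,FI,9,tool,sponge,typical,
B20,DA,4.8,tool,sponge,typical,
B21,AM,3.4,tool,sponge,typical,
B22,BA,2.6,tool,sponge,typical,
B23,DO,2,tool,stick_honey,typical,
B24,HA,13,tool,stick_honey,typical,
B25,BO,1,tool,stick_insect,atypical,omission
B26,BU,1,tool,stick_insect,atypical,commission
B27,HD,2,tool,stick_water,atypical,commission
B28,TO,3,tool,stick_water,atypical,commission
B29,CF,1,doll,,atypical,commission
B30,CF,1.2,doll,,atypical,commission
B31,IV,2,aggression,branch_shake,atypical,commission
B32,LU,2.5,aggression,branch_shake,typical,
B33,MA,3,aggression,branch_shake,typical,
B34,MI,4,aggression,branch_shake,typical,
B35,MO,2,aggression,stick_throw,atypical,commission
B36,NI,2.2,aggression,stick_throw,atypical,commission
B37,OT,2.8,aggression,stick_throw,typical,
B38,TO,2.8,game,,atypical,commission
B39,CF,1,game,,atypical,commission
B40,CF,1.6,game,,atypical,commission
B41,BB,3.2,game,,atypical,commission
B42,BB,3.6,game,,typical,
B43,CL,2.6,game,,atypical,commission
B44,CL,2.4,game,,typical,
B45,KO,2.5,game,,atypical,commission
B46,ZW,3.3,game,,atypical,commission
B47,RU,9,game,,atypical,commission
B48,NA1,5.2,game,,typical,
B49,OF,8,locomotion_aid,,atypical,commission
B50,SA,4,locomotion_aid,,typical,
B51,NA1,6,physical_stimulation,scratch_body,typical,
B52,PE,3,physical_stimulation,scratch_body,typical,
B53,AR,2.7,physical_stimulation,scratch_body,typical,
B54,KE,1,physical_stimulation,scratch_body,atypical,commission
B55,AZ,2.2,physical_stimulation,scratch_body,typical,
B56,NA1,6,physical_stimulation,masturbate,typical,
B57,KE,1.8,physical_stimulation,masturbate,atypical,commission
B58,AR,2.9,physical_stimulation,masturbate,atypical,commission
B59,KE,2,play_nest,,atypical,commission
B60,ZW,3.1,play_nest,,atypical,commission
B61,HD,2.4,play_nest,,atypical,commission
B62,CH,2.6,play_nest,,atypical,commission
B63,JO,3,play_nest,,atypical,commission
B64,JO,3.2,play_nest,,atypical,commission
B65,JO,3.4,play_nest,,atypical,commission
B66,AZ,2.8,play_nest,,typical,
B67,PE,3.3,play_nest,,typical,
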