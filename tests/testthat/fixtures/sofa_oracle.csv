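system,pao2_fio2_ratio,on_respiratory_support,platelets,bilirubin,map_mmHg,vasopressor,gcs,creatinine,urine_output_mL_day,expected
respiratory,450,FALSE,,,,,,,,0
respiratory,400,FALSE,,,,,,,,0
respiratory,399,FALSE,,,,,,,,1
respiratory,300,FALSE,,,,,,,,1
respiratory,299,FALSE,,,,,,,,2
respiratory,200,FALSE,,,,,,,,2
respiratory,199,FALSE,,,,,,,,2
respiratory,199,TRUE,,,,,,,,3
respiratory,100,TRUE,,,,,,,,3
respiratory,99,TRUE,,,,,,,,4
respiratory,99,FALSE,,,,,,,,2
coagulation,,,200,,,,,,,0
coagulation,,,151,,,,,,,0
coagulation,,,150,,,,,,,1
coagulation,,,101,,,,,,,1
coagulation,,,100,,,,,,,2
coagulation,,,51,,,,,,,2
coagulation,,,50,,,,,,,3
coagulation,,,21,,,,,,,3
coagulation,,,20,,,,,,,4
coagulation,,,10,,,,,,,4
liver,,,,1.0,,,,,,0
liver,,,,1.1,,,,,,0
liver,,,,1.2,,,,,,1
liver,,,,1.9,,,,,,1
liver,,,,2.0,,,,,,2
liver,,,,5.9,,,,,,2
liver,,,,6.0,,,,,,3
liver,,,,11.9,,,,,,3
liver,,,,12.0,,,,,,4
liver,,,,20,,,,,,4
cardiovascular,,,,,80,none,,,,0
cardiovascular,,,,,70,none,,,,0
cardiovascular,,,,,69,none,,,,1
cardiovascular,,,,,69,dopamine_low_or_dobutamine,,,,2
cardiovascular,,,,,80,dopamine_low_or_dobutamine,,,,2
cardiovascular,,,,,80,dopamine_mid_or_epi_norepi_low,,,,3
cardiovascular,,,,,65,dopamine_mid_or_epi_norepi_low,,,,3
cardiovascular,,,,,80,dopamine_high_or_epi_norepi_high,,,,4
cns,,,,,,,15,,,0
cns,,,,,,,14,,,1
cns,,,,,,,13,,,1
cns,,,,,,,12,,,2
cns,,,,,,,10,,,2
cns,,,,,,,9,,,3
cns,,,,,,,6,,,3
cns,,,,,,,5,,,4
cns,,,,,,,3,,,4
renal,,,,,,,,1.0,,0
renal,,,,,,,,1.1,,0
renal,,,,,,,,1.2,,1
renal,,,,,,,,1.9,,1
renal,,,,,,,,2.0,,2
renal,,,,,,,,3.4,,2
renal,,,,,,,,3.5,,3
renal,,,,,,,,4.9,,3
renal,,,,,,,,5.0,,4
renal,,,,,,,,8.0,,4
renal,,,,,,,,,500,0
renal,,,,,,,,,499,3
renal,,,,,,,,,200,3
renal,,,,,,,,,199,4
renal,,,,,,,,1.2,150,4
renal,,,,,,,,5.0,600,4
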