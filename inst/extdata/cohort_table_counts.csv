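variable,group,yes,no
male_sex,HC,9,7
male_sex,TC,25,2
male_sex,PTSD,10,9
veteran,HC,0,16
veteran,TC,24,3
veteran,PTSD,11,8
white_race,HC,10,6
white_race,TC,22,5
white_race,PTSD,16,3
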