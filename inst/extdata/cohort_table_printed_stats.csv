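variable,test,printed_value,printed_df,reproducible
age,anova_f,9.14,"2,59",TRUE
bmi,anova_f,3.17,"2,59",TRUE
male_sex,pearson_chi2,10.91,2,TRUE
veteran,pearson_chi2,32.31,2,TRUE
number_of_traumas,welch_t,2.27,10,TRUE
age_first_trauma,welch_t,0.75,16,TRUE
white_race,pearson_chi2,3.66,2,FALSE
injected_mass,anova_f,1.85,"2,59",FALSE
age_presenting_trauma,welch_t,1.59,25,FALSE
caps_total,welch_t,11.26,29,FALSE
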