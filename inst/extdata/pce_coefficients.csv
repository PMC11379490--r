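# ASCVD pooled cohort equations, race- and sex-specific Cox coefficients
# (2013 ACC/AHA risk assessment guideline, appendix coefficient tables)
# version: 1
group,term,value
white_female,ln_age,-29.799
white_female,ln_age_sq,4.884
white_female,ln_tc,13.540
white_female,ln_age_ln_tc,-3.114
white_female,ln_hdl,-13.578
white_female,ln_age_ln_hdl,3.149
white_female,ln_sbp_treated,2.019
white_female,ln_sbp_untreated,1.957
white_female,smoker,7.574
white_female,ln_age_smoker,-1.665
white_female,diabetes,0.661
white_female,mean_xb,-29.18
white_female,s10,0.9665
black_female,ln_age,17.114
black_female,ln_tc,0.940
black_female,ln_hdl,-18.920
black_female,ln_age_ln_hdl,4.475
black_female,ln_sbp_treated,29.291
black_female,ln_age_ln_sbp_treated,-6.432
black_female,ln_sbp_untreated,27.820
black_female,ln_age_ln_sbp_untreated,-6.087
black_female,smoker,0.691
black_female,diabetes,0.874
black_female,mean_xb,86.61
black_female,s10,0.9533
white_male,ln_age,12.344
white_male,ln_tc,11.853
white_male,ln_age_ln_tc,-2.664
white_male,ln_hdl,-7.990
white_male,ln_age_ln_hdl,1.769
white_male,ln_sbp_treated,1.797
white_male,ln_sbp_untreated,1.764
white_male,smoker,7.837
white_male,ln_age_smoker,-1.795
white_male,diabetes,0.658
white_male,mean_xb,61.18
white_male,s10,0.9144
black_male,ln_age,2.469
black_male,ln_tc,0.302
black_male,ln_hdl,-0.307
black_male,ln_sbp_treated,1.916
black_male,ln_sbp_untreated,1.809
black_male,smoker,0.549
black_male,diabetes,0.645
black_male,mean_xb,19.54
black_male,s10,0.8954
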