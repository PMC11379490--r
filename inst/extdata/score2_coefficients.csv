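# SCORE2 sex-specific Cox coefficients on transformed risk factors
# (2021 ESC working group publication, supplementary tables). Transforms:
# cage=(age-60)/5, csbp=(sbp-120)/20, ctchol=(tchol-6)/1, chdl=(hdl-1.3)/0.5
# s10 is the 10-year baseline survival of the uncalibrated model.
# version: 1
sex,term,value
male,cage,0.3742
male,smoker,0.6012
male,csbp,0.2777
male,ctchol,0.1458
male,chdl,-0.2698
male,smoker_cage,-0.0755
male,csbp_cage,-0.0255
male,ctchol_cage,-0.0281
male,chdl_cage,0.0426
male,s10,0.9605
female,cage,0.4648
female,smoker,0.7744
female,csbp,0.3131
female,ctchol,0.1002
female,chdl,-0.2606
female,smoker_cage,-0.1088
female,csbp_cage,-0.0277
female,ctchol_cage,-0.0226
female,chdl_cage,0.0613
female,s10,0.9776
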