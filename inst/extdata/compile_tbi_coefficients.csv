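term,model,outcome,median,lo,hi
diabetes_pulmonary,univariate,ordinal,-0.37,-1.11,0.37
cardiovascular,univariate,ordinal,-0.26,-0.51,-0.01
blood_type_a_ab,univariate,ordinal,-0.28,-0.58,0.03
ox_high_flow_age67,univariate,ordinal,0.31,-0.28,0.91
ox_mask_age67,univariate,ordinal,0.12,-0.22,0.45
ox_high_flow,univariate,ordinal,0.24,-0.31,0.80
ox_mask,univariate,ordinal,0.32,-0.09,0.72
ccp_treatment,univariate,ordinal,-0.18,-0.55,0.19
diabetes_pulmonary,multivariate,ordinal,-0.51,-1.05,0.06
cardiovascular,multivariate,ordinal,-0.32,-0.51,-0.11
blood_type_a_ab,multivariate,ordinal,-0.37,-0.62,-0.09
ox_high_flow_age67,multivariate,ordinal,0.41,-0.01,0.81
ox_mask_age67,multivariate,ordinal,0.05,-0.22,0.31
ox_high_flow,multivariate,ordinal,0.54,0.12,0.94
ox_mask,multivariate,ordinal,0.67,0.34,0.99
ccp_treatment,multivariate,ordinal,-0.39,-0.68,-0.11
diabetes_pulmonary,multivariate,binary1,-0.51,-1.10,0.18
cardiovascular,multivariate,binary1,-0.35,-0.59,-0.11
blood_type_a_ab,multivariate,binary1,-0.47,-0.82,-0.19
ox_high_flow_age67,multivariate,binary1,0.46,0.03,0.93
ox_mask_age67,multivariate,binary1,0.06,-0.24,0.40
ox_high_flow,multivariate,binary1,0.56,0.12,1.00
ox_mask,multivariate,binary1,0.75,0.40,1.16
ccp_treatment,multivariate,binary1,-0.41,-0.73,-0.10
diabetes_pulmonary,multivariate,binary2,-0.61,-1.37,0.00
cardiovascular,multivariate,binary2,-0.37,-0.67,-0.15
blood_type_a_ab,multivariate,binary2,-0.49,-0.89,-0.20
ox_high_flow_age67,multivariate,binary2,0.46,0.03,0.92
ox_mask_age67,multivariate,binary2,-0.02,-0.42,0.28
ox_high_flow,multivariate,binary2,0.59,0.15,1.04
ox_mask,multivariate,binary2,0.75,0.37,1.16
ccp_treatment,multivariate,binary2,-0.41,-0.74,-0.10
diabetes_pulmonary,multivariate,binary3,-0.65,-1.56,-0.06
cardiovascular,multivariate,binary3,-0.37,-0.68,-0.14
blood_type_a_ab,multivariate,binary3,-0.43,-0.78,-0.12
ox_high_flow_age67,multivariate,binary3,0.43,-0.05,0.87
ox_mask_age67,multivariate,binary3,-0.01,-0.42,0.29
ox_high_flow,multivariate,binary3,0.56,0.11,1.01
ox_mask,multivariate,binary3,0.71,0.32,1.11
ccp_treatment,multivariate,binary3,-0.44,-0.80,-0.13
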