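stratum,sex,age_band,mean_t2dm,mean_non_t2dm,printed_ratio
sex_age,male,65-69,1183.43,683.85,1.73
sex_age,male,70-74,1184.35,744.02,1.59
sex_age,male,>=75,1245.51,871.33,1.45
sex_age,female,65-69,1223.89,667.52,1.83
sex_age,female,70-74,1293.06,764.89,1.69
sex_age,female,>=75,1279.10,882.95,1.45
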