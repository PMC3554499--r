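sex,age_band,group,n
male,65-69,t2dm,5535
male,70-74,t2dm,6948
male,>=75,t2dm,10690
female,65-69,t2dm,4610
female,70-74,t2dm,5109
female,>=75,t2dm,10273
male,65-69,non_t2dm,38606
male,70-74,non_t2dm,50023
male,>=75,non_t2dm,79888
female,65-69,non_t2dm,52770
female,70-74,non_t2dm,57726
female,>=75,non_t2dm,123002
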