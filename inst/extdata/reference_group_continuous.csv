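variable,group,mean,sd,n
age,BD,52.11,7.31,4830
age,UM,54.05,7.76,1200
age,CONTROL,57.06,7.56,58238
townsend,BD,-1.02,3.16,4830
townsend,UM,-1.71,2.82,1200
townsend,CONTROL,-2.00,2.67,58238
bmi,BD,27.81,5.19,4830
bmi,UM,27.25,4.36,1200
bmi,CONTROL,26.53,4.14,58238
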