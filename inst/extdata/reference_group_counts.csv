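variable,category,BD,UM,CONTROL
sex,Female,2978,470,27166
sex,Male,1852,730,31072
education,Incomplete,295,43,4703
education,Compulsory,722,145,8336
education,Continued,353,83,3498
education,College,1398,338,15612
education,University,2030,586,25521
ethnicity,White,4637,1146,56374
ethnicity,Mixed,55,7,214
ethnicity,Asian,47,17,569
ethnicity,Black,41,11,489
ethnicity,Chinese,8,2,159
ethnicity,Other,27,13,277
smoking,Never,2321,667,35714
smoking,Previous,1790,444,19206
smoking,Current,706,88,3194
alcohol,Never,118,25,1753
alcohol,Previous,270,31,1114
alcohol,Current,4438,1144,55330
psychotropic,Yes,182,4,191
psychotropic,No,4648,1196,58047
anxiety,Yes,3122,173,2917
anxiety,No,1088,950,48183
objective_sleep,Short,698,210,7695
objective_sleep,Regular,1153,283,14964
objective_sleep,Long,38,2,345
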