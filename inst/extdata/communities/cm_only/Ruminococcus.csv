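group,param,pathway,units,resistant_starch,water,acetate,CO2,formate,H2
Ruminococcus,Rtype,rs_degradation,,S,Sw,P,P,P,P
Ruminococcus,molarMass,rs_degradation,g/mol,162.14,18.015,60.05,44.01,46.03,2.016
Ruminococcus,numMolecules,rs_degradation,count,1,1,,,,
Ruminococcus,stoichiomProduct,rs_degradation,count,,,2,1,1,4
Ruminococcus,halfSat,rs_degradation,g/L,0.006,,,,,
Ruminococcus,yield,rs_degradation,g/g,0.333,,,,,
Ruminococcus,maxGrowthRate,rs_degradation,1/h,0.35,0.35,0.35,0.35,0.35,0.35
Ruminococcus,pHcorner1,,pH,5,5,5,5,5,5
Ruminococcus,pHcorner2,,pH,5.8,5.8,5.8,5.8,5.8,5.8
Ruminococcus,pHcorner3,,pH,7,7,7,7,7,7
Ruminococcus,pHcorner4,,pH,8,8,8,8,8,8
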