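group,param,pathway,units,sugars,water,acetate,butyrate,CO2,H2
Clostridium,Rtype,sugar_fermentation,,S,Sw,P,P,P,P
Clostridium,molarMass,sugar_fermentation,g/mol,180.16,18.015,60.05,88.11,44.01,2.016
Clostridium,numMolecules,sugar_fermentation,count,1,1,,,,
Clostridium,stoichiomProduct,sugar_fermentation,count,,,1,1,2,2
Clostridium,halfSat,sugar_fermentation,g/L,0.06,,,,,
Clostridium,yield,sugar_fermentation,g/g,0.333,,,,,
Clostridium,maxGrowthRate,sugar_fermentation,1/h,0.5,0.5,0.5,0.5,0.5,0.5
Clostridium,pHcorner1,,pH,4.7,4.7,4.7,4.7,4.7,4.7
Clostridium,pHcorner2,,pH,5.5,5.5,5.5,5.5,5.5,5.5
Clostridium,pHcorner3,,pH,7.5,7.5,7.5,7.5,7.5,7.5
Clostridium,pHcorner4,,pH,8.5,8.5,8.5,8.5,8.5,8.5
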