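group,param,pathway,units,NSP,water,acetate,CO2,propionate,succinate,protein,isovalerate
Parabacteroides,Rtype,nsp_degradation,,S,Sw,P,P,P,P,,
Parabacteroides,molarMass,nsp_degradation,g/mol,162.14,18.015,60.05,44.01,74.08,118.09,,
Parabacteroides,numMolecules,nsp_degradation,count,1,1,,,,,,
Parabacteroides,stoichiomProduct,nsp_degradation,count,,,1,1,1,1,,
Parabacteroides,halfSat,nsp_degradation,g/L,0.1,,,,,,,
Parabacteroides,yield,nsp_degradation,g/g,0.333,,,,,,,
Parabacteroides,maxGrowthRate,nsp_degradation,1/h,0.3,0.3,0.3,0.3,0.3,0.3,,
Parabacteroides,Rtype,proteolysis,,,,P,P,P,,S,P
Parabacteroides,molarMass,proteolysis,g/mol,,,60.05,44.01,74.08,,110,102.13
Parabacteroides,numMolecules,proteolysis,count,,,,,,,1,
Parabacteroides,stoichiomProduct,proteolysis,count,,,1,1,1,,,1
Parabacteroides,halfSat,proteolysis,g/L,,,,,,,0.2,
Parabacteroides,yield,proteolysis,g/g,,,,,,,0.3,
Parabacteroides,maxGrowthRate,proteolysis,1/h,,,0.2,0.2,0.2,,0.2,0.2
Parabacteroides,pHcorner1,,pH,4.9,4.9,4.9,4.9,4.9,4.9,4.9,4.9
Parabacteroides,pHcorner2,,pH,5.7,5.7,5.7,5.7,5.7,5.7,5.7,5.7
Parabacteroides,pHcorner3,,pH,7.3,7.3,7.3,7.3,7.3,7.3,7.3,7.3
Parabacteroides,pHcorner4,,pH,8.3,8.3,8.3,8.3,8.3,8.3,8.3,8.3
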