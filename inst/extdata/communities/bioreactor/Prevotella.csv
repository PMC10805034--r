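group,param,pathway,units,NSP,water,acetate,CO2,H2,propionate,succinate,sugars
Prevotella,Rtype,nsp_fermentation,,S,Sw,P,P,P,P,P,
Prevotella,molarMass,nsp_fermentation,g/mol,162.14,18.015,60.05,44.01,2.016,74.08,118.09,
Prevotella,numMolecules,nsp_fermentation,count,1,1,,,,,,
Prevotella,stoichiomProduct,nsp_fermentation,count,,,1,1,2,1,1,
Prevotella,halfSat,nsp_fermentation,g/L,0.004,,,,,,,
Prevotella,yield,nsp_fermentation,g/g,0.333,,,,,,,
Prevotella,maxGrowthRate,nsp_fermentation,1/h,0.45,0.45,0.45,0.45,0.45,0.45,0.45,
Prevotella,Rtype,sugar_fermentation,,,Sw,P,P,,,P,S
Prevotella,molarMass,sugar_fermentation,g/mol,,18.015,60.05,44.01,,,118.09,180.16
Prevotella,numMolecules,sugar_fermentation,count,,1,,,,,,1
Prevotella,stoichiomProduct,sugar_fermentation,count,,,2,1,,,1,
Prevotella,halfSat,sugar_fermentation,g/L,,,,,,,,0.08
Prevotella,yield,sugar_fermentation,g/g,,,,,,,,0.333
Prevotella,maxGrowthRate,sugar_fermentation,1/h,,0.15,0.15,0.15,,,0.15,0.15
Prevotella,pHcorner1,,pH,4.8,4.8,4.8,4.8,4.8,4.8,4.8,4.8
Prevotella,pHcorner2,,pH,5.6,5.6,5.6,5.6,5.6,5.6,5.6,5.6
Prevotella,pHcorner3,,pH,7.2,7.2,7.2,7.2,7.2,7.2,7.2,7.2
Prevotella,pHcorner4,,pH,8.2,8.2,8.2,8.2,8.2,8.2,8.2,8.2
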