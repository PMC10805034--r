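group,param,pathway,units,lactate,butyrate,CO2,H2,propionate,valerate,sugars,water,caproate
Megasphaera,Rtype,lactate_conversion,,S,P,P,P,P,P,,,
Megasphaera,molarMass,lactate_conversion,g/mol,90.08,88.11,44.01,2.016,74.08,102.13,,,
Megasphaera,numMolecules,lactate_conversion,count,3,,,,,,,,
Megasphaera,stoichiomProduct,lactate_conversion,count,,1,1,1,2,1,,,
Megasphaera,halfSat,lactate_conversion,g/L,0.001,,,,,,,,
Megasphaera,yield,lactate_conversion,g/g,0.333,,,,,,,,
Megasphaera,maxGrowthRate,lactate_conversion,1/h,0.5,0.5,0.5,0.5,0.5,0.5,,,
Megasphaera,Rtype,sugar_fermentation,,,P,P,P,,,S,Sw,P
Megasphaera,molarMass,sugar_fermentation,g/mol,,88.11,44.01,2.016,,,180.16,18.015,116.16
Megasphaera,numMolecules,sugar_fermentation,count,,,,,,,1,1,
Megasphaera,stoichiomProduct,sugar_fermentation,count,,1,1,2,,,,,1
Megasphaera,halfSat,sugar_fermentation,g/L,,,,,,,0.05,,
Megasphaera,yield,sugar_fermentation,g/g,,,,,,,0.333,,
Megasphaera,maxGrowthRate,sugar_fermentation,1/h,,0.2,0.2,0.2,,,0.2,0.2,0.2
Megasphaera,pHcorner1,,pH,4.9,4.9,4.9,4.9,4.9,4.9,4.9,4.9,4.9
Megasphaera,pHcorner2,,pH,5.7,5.7,5.7,5.7,5.7,5.7,5.7,5.7,5.7
Megasphaera,pHcorner3,,pH,7.4,7.4,7.4,7.4,7.4,7.4,7.4,7.4,7.4
Megasphaera,pHcorner4,,pH,8.4,8.4,8.4,8.4,8.4,8.4,8.4,8.4,8.4
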