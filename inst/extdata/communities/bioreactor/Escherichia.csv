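group,param,pathway,units,sugars,acetate,CO2,ethanol,formate,H2
Escherichia,Rtype,mixed_acid_fermentation,,S,P,P,P,P,P
Escherichia,molarMass,mixed_acid_fermentation,g/mol,180.16,60.05,44.01,46.07,46.03,2.016
Escherichia,numMolecules,mixed_acid_fermentation,count,1,,,,,
Escherichia,stoichiomProduct,mixed_acid_fermentation,count,,1,1,1,2,1
Escherichia,halfSat,mixed_acid_fermentation,g/L,0.04,,,,,
Escherichia,yield,mixed_acid_fermentation,g/g,0.333,,,,,
Escherichia,maxGrowthRate,mixed_acid_fermentation,1/h,0.6,0.6,0.6,0.6,0.6,0.6
Escherichia,pHcorner1,,pH,5.5,5.5,5.5,5.5,5.5,5.5
Escherichia,pHcorner2,,pH,6.9,6.9,6.9,6.9,6.9,6.9
Escherichia,pHcorner3,,pH,8,8,8,8,8,8
Escherichia,pHcorner4,,pH,9,9,9,9,9,9
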