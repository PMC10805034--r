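group,param,pathway,units,sugars,acetate,lactate
Turicibacter,Rtype,sugar_fermentation,,S,P,P
Turicibacter,molarMass,sugar_fermentation,g/mol,180.16,60.05,90.08
Turicibacter,numMolecules,sugar_fermentation,count,1,,
Turicibacter,stoichiomProduct,sugar_fermentation,count,,1,2
Turicibacter,halfSat,sugar_fermentation,g/L,0.1,,
Turicibacter,yield,sugar_fermentation,g/g,0.333,,
Turicibacter,maxGrowthRate,sugar_fermentation,1/h,0.25,0.25,0.25
Turicibacter,pHcorner1,,pH,5.1,5.1,5.1
Turicibacter,pHcorner2,,pH,5.9,5.9,5.9
Turicibacter,pHcorner3,,pH,7.1,7.1,7.1
Turicibacter,pHcorner4,,pH,8.1,8.1,8.1
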