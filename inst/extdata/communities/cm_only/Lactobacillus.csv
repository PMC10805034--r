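group,param,pathway,units,sugars,acetate,CO2,ethanol,lactate
Lactobacillus,Rtype,heterolactic_fermentation,,S,P,P,P,P
Lactobacillus,molarMass,heterolactic_fermentation,g/mol,180.16,60.05,44.01,46.07,90.08
Lactobacillus,numMolecules,heterolactic_fermentation,count,1,,,,
Lactobacillus,stoichiomProduct,heterolactic_fermentation,count,,1,1,1,1
Lactobacillus,halfSat,heterolactic_fermentation,g/L,0.02,,,,
Lactobacillus,yield,heterolactic_fermentation,g/g,0.333,,,,
Lactobacillus,maxGrowthRate,heterolactic_fermentation,1/h,0.4,0.4,0.4,0.4,0.4
Lactobacillus,pHcorner1,,pH,4,4,4,4,4
Lactobacillus,pHcorner2,,pH,4.8,4.8,4.8,4.8,4.8
Lactobacillus,pHcorner3,,pH,6.8,6.8,6.8,6.8,6.8
Lactobacillus,pHcorner4,,pH,7.8,7.8,7.8,7.8,7.8
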