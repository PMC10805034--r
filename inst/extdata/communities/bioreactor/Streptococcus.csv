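group,param,pathway,units,sugars,formate,lactate
Streptococcus,Rtype,homolactic_fermentation,,S,P,P
Streptococcus,molarMass,homolactic_fermentation,g/mol,180.16,46.03,90.08
Streptococcus,numMolecules,homolactic_fermentation,count,1,,
Streptococcus,stoichiomProduct,homolactic_fermentation,count,,1,2
Streptococcus,halfSat,homolactic_fermentation,g/L,0.03,,
Streptococcus,yield,homolactic_fermentation,g/g,0.333,,
Streptococcus,maxGrowthRate,homolactic_fermentation,1/h,0.45,0.45,0.45
Streptococcus,pHcorner1,,pH,4.6,4.6,4.6
Streptococcus,pHcorner2,,pH,5.4,5.4,5.4
Streptococcus,pHcorner3,,pH,7.6,7.6,7.6
Streptococcus,pHcorner4,,pH,8.6,8.6,8.6
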