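group,param,pathway,units,resistant_starch,water,acetate,butyrate,CO2,formate
Faecalibacterium,Rtype,butyrogenic_rs_fermentation,,S,Sw,Sb,P,P,P
Faecalibacterium,molarMass,butyrogenic_rs_fermentation,g/mol,162.14,18.015,60.05,88.11,44.01,46.03
Faecalibacterium,numMolecules,butyrogenic_rs_fermentation,count,1,1,1,,,
Faecalibacterium,stoichiomProduct,butyrogenic_rs_fermentation,count,,,,2,1,1
Faecalibacterium,halfSat,butyrogenic_rs_fermentation,g/L,0.05,,0.4,,,
Faecalibacterium,yield,butyrogenic_rs_fermentation,g/g,0.333,,,,,
Faecalibacterium,maxGrowthRate,butyrogenic_rs_fermentation,1/h,0.35,0.35,0.35,0.35,0.35,0.35
Faecalibacterium,pHcorner1,,pH,4.9,4.9,4.9,4.9,4.9,4.9
Faecalibacterium,pHcorner2,,pH,5.7,5.7,5.7,5.7,5.7,5.7
Faecalibacterium,pHcorner3,,pH,7,7,7,7,7,7
Faecalibacterium,pHcorner4,,pH,8,8,8,8,8,8
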