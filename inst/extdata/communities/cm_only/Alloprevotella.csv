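group,param,pathway,units,NSP,water,acetate,CO2,succinate
Alloprevotella,Rtype,nsp_degradation,,S,Sw,P,P,P
Alloprevotella,molarMass,nsp_degradation,g/mol,162.14,18.015,60.05,44.01,118.09
Alloprevotella,numMolecules,nsp_degradation,count,1,1,,,
Alloprevotella,stoichiomProduct,nsp_degradation,count,,,2,1,1
Alloprevotella,halfSat,nsp_degradation,g/L,0.03,,,,
Alloprevotella,yield,nsp_degradation,g/g,0.333,,,,
Alloprevotella,maxGrowthRate,nsp_degradation,1/h,0.3,0.3,0.3,0.3,0.3
Alloprevotella,pHcorner1,,pH,4.8,4.8,4.8,4.8,4.8
Alloprevotella,pHcorner2,,pH,5.6,5.6,5.6,5.6,5.6
Alloprevotella,pHcorner3,,pH,7.2,7.2,7.2,7.2,7.2
Alloprevotella,pHcorner4,,pH,8.2,8.2,8.2,8.2,8.2
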