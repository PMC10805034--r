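group,param,pathway,units,CO2,H2,acetate
Blautia,Rtype,acetogenesis,,Se,Se,P
Blautia,molarMass,acetogenesis,g/mol,44.01,2.016,60.05
Blautia,numMolecules,acetogenesis,count,2,4,
Blautia,stoichiomProduct,acetogenesis,count,,,1
Blautia,halfSat,acetogenesis,g/L,0.001,0.0001,
Blautia,yield,acetogenesis,g/g,0.1,0.3,
Blautia,maxGrowthRate,acetogenesis,1/h,0.4,0.4,0.4
Blautia,pHcorner1,,pH,4.8,4.8,4.8
Blautia,pHcorner2,,pH,5.6,5.6,5.6
Blautia,pHcorner3,,pH,7.2,7.2,7.2
Blautia,pHcorner4,,pH,8.2,8.2,8.2
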