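group,param,pathway,units,NSP,water,acetate,CO2,H2,propionate
RC9,Rtype,nsp_degradation,,S,Sw,P,P,P,P
RC9,molarMass,nsp_degradation,g/mol,162.14,18.015,60.05,44.01,2.016,74.08
RC9,numMolecules,nsp_degradation,count,1,1,,,,
RC9,stoichiomProduct,nsp_degradation,count,,,2,1,1,1
RC9,halfSat,nsp_degradation,g/L,0.05,,,,,
RC9,yield,nsp_degradation,g/g,0.333,,,,,
RC9,maxGrowthRate,nsp_degradation,1/h,0.3,0.3,0.3,0.3,0.3,0.3
RC9,pHcorner1,,pH,5,5,5,5,5,5
RC9,pHcorner2,,pH,5.9,5.9,5.9,5.9,5.9,5.9
RC9,pHcorner3,,pH,7.1,7.1,7.1,7.1,7.1,7.1
RC9,pHcorner4,,pH,8.1,8.1,8.1,8.1,8.1,8.1
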