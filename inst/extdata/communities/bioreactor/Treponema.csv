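group,param,pathway,units,NSP,water,acetate,CO2,ethanol,H2
Treponema,Rtype,nsp_degradation,,S,Sw,P,P,P,P
Treponema,molarMass,nsp_degradation,g/mol,162.14,18.015,60.05,44.01,46.07,2.016
Treponema,numMolecules,nsp_degradation,count,1,1,,,,
Treponema,stoichiomProduct,nsp_degradation,count,,,2,1,1,1
Treponema,halfSat,nsp_degradation,g/L,0.08,,,,,
Treponema,yield,nsp_degradation,g/g,0.333,,,,,
Treponema,maxGrowthRate,nsp_degradation,1/h,0.25,0.25,0.25,0.25,0.25,0.25
Treponema,pHcorner1,,pH,5.2,5.2,5.2,5.2,5.2,5.2
Treponema,pHcorner2,,pH,6,6,6,6,6,6
Treponema,pHcorner3,,pH,7.4,7.4,7.4,7.4,7.4,7.4
Treponema,pHcorner4,,pH,8.4,8.4,8.4,8.4,8.4,8.4
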