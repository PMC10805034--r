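group,param,pathway,units,sugars,water,acetate,CO2,propionate,succinate,resistant_starch
Succinivibrio,Rtype,sugar_fermentation,,S,Sw,P,P,P,P,
Succinivibrio,molarMass,sugar_fermentation,g/mol,180.16,18.015,60.05,44.01,74.08,118.09,
Succinivibrio,numMolecules,sugar_fermentation,count,1,1,,,,,
Succinivibrio,stoichiomProduct,sugar_fermentation,count,,,2,1,1,1,
Succinivibrio,halfSat,sugar_fermentation,g/L,0.01,,,,,,
Succinivibrio,yield,sugar_fermentation,g/g,0.333,,,,,,
Succinivibrio,maxGrowthRate,sugar_fermentation,1/h,0.5,0.5,0.5,0.5,0.5,0.5,
Succinivibrio,Rtype,rs_degradation,,,Sw,P,P,,P,S
Succinivibrio,molarMass,rs_degradation,g/mol,,18.015,60.05,44.01,,118.09,162.14
Succinivibrio,numMolecules,rs_degradation,count,,1,,,,,1
Succinivibrio,stoichiomProduct,rs_degradation,count,,,2,1,,1,
Succinivibrio,halfSat,rs_degradation,g/L,,,,,,,0.08
Succinivibrio,yield,rs_degradation,g/g,,,,,,,0.333
Succinivibrio,maxGrowthRate,rs_degradation,1/h,,0.2,0.2,0.2,,0.2,0.2
Succinivibrio,pHcorner1,,pH,4.9,4.9,4.9,4.9,4.9,4.9,4.9
Succinivibrio,pHcorner2,,pH,5.7,5.7,5.7,5.7,5.7,5.7,5.7
Succinivibrio,pHcorner3,,pH,7.3,7.3,7.3,7.3,7.3,7.3,7.3
Succinivibrio,pHcorner4,,pH,8.3,8.3,8.3,8.3,8.3,8.3,8.3
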