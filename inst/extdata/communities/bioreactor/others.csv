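group,param,pathway,units,protein,water,acetate,butyrate,CO2,H2,isovalerate,propionate,NSP,succinate,resistant_starch,formate,sugars,ethanol,lactate,CH4
others,Rtype,proteolysis,,S,Sw,P,P,P,P,P,P,,,,,,,,
others,molarMass,proteolysis,g/mol,110,18.015,60.05,88.11,44.01,2.016,102.13,74.08,,,,,,,,
others,numMolecules,proteolysis,count,1,1,,,,,,,,,,,,,,
others,stoichiomProduct,proteolysis,count,,,1,2,1,1,1,1,,,,,,,,
others,halfSat,proteolysis,g/L,0.04,,,,,,,,,,,,,,,
others,yield,proteolysis,g/g,0.3,,,,,,,,,,,,,,,
others,maxGrowthRate,proteolysis,1/h,0.6,0.6,0.6,0.6,0.6,0.6,0.6,0.6,,,,,,,,
others,Rtype,nsp_degradation,,,Sw,P,,P,P,,,S,P,,,,,,
others,molarMass,nsp_degradation,g/mol,,18.015,60.05,,44.01,2.016,,,162.14,118.09,,,,,,
others,numMolecules,nsp_degradation,count,,1,,,,,,,1,,,,,,,
others,stoichiomProduct,nsp_degradation,count,,,2,,1,1,,,,1,,,,,,
others,halfSat,nsp_degradation,g/L,,,,,,,,,0.25,,,,,,,
others,yield,nsp_degradation,g/g,,,,,,,,,0.333,,,,,,,
others,maxGrowthRate,nsp_degradation,1/h,,0.25,0.25,,0.25,0.25,,,0.25,0.25,,,,,,
others,Rtype,rs_degradation,,,Sw,P,,P,P,,,,,S,P,,,,
others,molarMass,rs_degradation,g/mol,,18.015,60.05,,44.01,2.016,,,,,162.14,46.03,,,,
others,numMolecules,rs_degradation,count,,1,,,,,,,,,1,,,,,
others,stoichiomProduct,rs_degradation,count,,,2,,1,1,,,,,,1,,,,
others,halfSat,rs_degradation,g/L,,,,,,,,,,,0.3,,,,,
others,yield,rs_degradation,g/g,,,,,,,,,,,0.333,,,,,
others,maxGrowthRate,rs_degradation,1/h,,0.25,0.25,,0.25,0.25,,,,,0.25,0.25,,,,
others,Rtype,lactate_producing_fermentation,,,,P,,,,,,,,,,S,P,P,
others,molarMass,lactate_producing_fermentation,g/mol,,,60.05,,,,,,,,,,180.16,46.07,90.08,
others,numMolecules,lactate_producing_fermentation,count,,,,,,,,,,,,,1,,,
others,stoichiomProduct,lactate_producing_fermentation,count,,,1,,,,,,,,,,,1,2,
others,halfSat,lactate_producing_fermentation,g/L,,,,,,,,,,,,,0.25,,,
others,yield,lactate_producing_fermentation,g/g,,,,,,,,,,,,,0.333,,,
others,maxGrowthRate,lactate_producing_fermentation,1/h,,,0.3,,,,,,,,,,0.3,0.3,0.3,
others,Rtype,lactate_to_butyrate,,,,,P,P,P,,,,,,,,,S,
others,molarMass,lactate_to_butyrate,g/mol,,,,88.11,44.01,2.016,,,,,,,,,90.08,
others,numMolecules,lactate_to_butyrate,count,,,,,,,,,,,,,,,3,
others,stoichiomProduct,lactate_to_butyrate,count,,,,2,1,2,,,,,,,,,,
others,halfSat,lactate_to_butyrate,g/L,,,,,,,,,,,,,,,0.3,
others,yield,lactate_to_butyrate,g/g,,,,,,,,,,,,,,,0.333,
others,maxGrowthRate,lactate_to_butyrate,1/h,,,,0.15,0.15,0.15,,,,,,,,,0.15,
others,Rtype,succinate_to_propionate,,,,,,P,,,P,,S,,,,,,
others,molarMass,succinate_to_propionate,g/mol,,,,,44.01,,,74.08,,118.09,,,,,,
others,numMolecules,succinate_to_propionate,count,,,,,,,,,,1,,,,,,
others,stoichiomProduct,succinate_to_propionate,count,,,,,1,,,1,,,,,,,,
others,halfSat,succinate_to_propionate,g/L,,,,,,,,,,0.05,,,,,,
others,yield,succinate_to_propionate,g/g,,,,,,,,,,0.333,,,,,,
others,maxGrowthRate,succinate_to_propionate,1/h,,,,,0.3,,,0.3,,0.3,,,,,,
others,Rtype,methanogenesis,,,,,,Se,Se,,,,,,,,,,P
others,molarMass,methanogenesis,g/mol,,,,,44.01,2.016,,,,,,,,,,16.04
others,numMolecules,methanogenesis,count,,,,,1,4,,,,,,,,,,
others,stoichiomProduct,methanogenesis,count,,,,,,,,,,,,,,,,1
others,halfSat,methanogenesis,g/L,,,,,0.05,0.05,,,,,,,,,,
others,yield,methanogenesis,g/g,,,,,0.1,0.1,,,,,,,,,,
others,maxGrowthRate,methanogenesis,1/h,,,,,0.1,0.1,,,,,,,,,,0.1
others,Rtype,homoacetogenesis,,,,P,,Se,Se,,,,,,,,,,
others,molarMass,homoacetogenesis,g/mol,,,60.05,,44.01,2.016,,,,,,,,,,
others,numMolecules,homoacetogenesis,count,,,,,2,4,,,,,,,,,,
others,stoichiomProduct,homoacetogenesis,count,,,1,,,,,,,,,,,,,
others,halfSat,homoacetogenesis,g/L,,,,,0.08,0.08,,,,,,,,,,
others,yield,homoacetogenesis,g/g,,,,,0.1,0.3,,,,,,,,,,
others,maxGrowthRate,homoacetogenesis,1/h,,,0.08,,0.08,0.08,,,,,,,,,,
others,Rtype,butyrogenesis,,,Sw,Sb,P,P,P,,,,,,,S,,,
others,molarMass,butyrogenesis,g/mol,,18.015,60.05,88.11,44.01,2.016,,,,,,,180.16,,,
others,numMolecules,butyrogenesis,count,,1,1,,,,,,,,,,1,,,
others,stoichiomProduct,butyrogenesis,count,,,,2,2,2,,,,,,,,,,
others,halfSat,butyrogenesis,g/L,,,0.5,,,,,,,,,,0.35,,,
others,yield,butyrogenesis,g/g,,,,,,,,,,,,,0.333,,,
others,maxGrowthRate,butyrogenesis,1/h,,0.2,0.2,0.2,0.2,0.2,,,,,,,0.2,,,
others,Rtype,ethanol_fermentation,,,,,,P,,,,,,,,S,P,,
others,molarMass,ethanol_fermentation,g/mol,,,,,44.01,,,,,,,,180.16,46.07,,
others,numMolecules,ethanol_fermentation,count,,,,,,,,,,,,,1,,,
others,stoichiomProduct,ethanol_fermentation,count,,,,,2,,,,,,,,,2,,
others,halfSat,ethanol_fermentation,g/L,,,,,,,,,,,,,0.4,,,
others,yield,ethanol_fermentation,g/g,,,,,,,,,,,,,0.333,,,
others,maxGrowthRate,ethanol_fermentation,1/h,,,,,0.15,,,,,,,,0.15,0.15,,
others,pHcorner1,,pH,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5,4.5
others,pHcorner2,,pH,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5,5.5
others,pHcorner3,,pH,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5,7.5
others,pHcorner4,,pH,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5,8.5
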