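group,param,pathway,units,succinate,CO2,propionate
Phascolarctobacterium,Rtype,succinate_to_propionate,,S,P,P
Phascolarctobacterium,molarMass,succinate_to_propionate,g/mol,118.09,44.01,74.08
Phascolarctobacterium,numMolecules,succinate_to_propionate,count,1,,
Phascolarctobacterium,stoichiomProduct,succinate_to_propionate,count,,1,1
Phascolarctobacterium,halfSat,succinate_to_propionate,g/L,0.01,,
Phascolarctobacterium,yield,succinate_to_propionate,g/g,0.333,,
Phascolarctobacterium,maxGrowthRate,succinate_to_propionate,1/h,0.132,0.132,0.132
Phascolarctobacterium,pHcorner1,,pH,5.2,5.2,5.2
Phascolarctobacterium,pHcorner2,,pH,6.8,6.8,6.8
Phascolarctobacterium,pHcorner3,,pH,7.6,7.6,7.6
Phascolarctobacterium,pHcorner4,,pH,8.6,8.6,8.6
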