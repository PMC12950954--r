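name_a,smiles_a,name_b,smiles_b,printed_tc,panel
bd_b10,CNCc1ccc(-c2cccnc2)s1,trigonelline,C[n+]1cccc(C(=O)[O-])c1,0.61,akt_inhibitors
bd_b10,CNCc1ccc(-c2cccnc2)s1,sc66,O=C1C(=Cc2ccncc2)CCCC1=Cc2ccncc2,0.55,akt_inhibitors
bd_b10,CNCc1ccc(-c2cccnc2)s1,honokiol,Oc1ccc(CC=C)cc1-c1ccc(O)c(CC=C)c1,0.54,akt_inhibitors
bd_b10,CNCc1ccc(-c2cccnc2)s1,loureirin_a,COc1ccc(CCC(=O)c2ccc(O)cc2)c(OC)c1,0.53,akt_inhibitors
bd_b10,CNCc1ccc(-c2cccnc2)s1,isc4,[Se]=C=NCCCCc1ccccc1,0.51,akt_inhibitors
bd_b10,CNCc1ccc(-c2cccnc2)s1,tryptamine,NCCc1c[nH]c2ccccc12,0.68,natural_metabolites
bd_b10,CNCc1ccc(-c2cccnc2)s1,n_methylserotonin,CNCCc1c[nH]c2ccc(O)cc12,0.67,natural_metabolites
bd_b10,CNCc1ccc(-c2cccnc2)s1,serotonin_1plus,[NH3+]CCc1c[nH]c2ccc(O)cc12,0.65,natural_metabolites
bd_b10,CNCc1ccc(-c2cccnc2)s1,metanephrine,CNCC(O)c1ccc(O)c(OC)c1,0.65,natural_metabolites
bd_b10,CNCc1ccc(-c2cccnc2)s1,indol3ylacetaldehyde,O=CCc1c[nH]c2ccccc12,0.65,natural_metabolites
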