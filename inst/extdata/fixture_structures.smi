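CNCc1ccc(-c2cccnc2)s1	bd_b10
C[n+]1cccc(C(=O)[O-])c1	trigonelline
O=C1C(=Cc2ccncc2)CCCC1=Cc2ccncc2	sc66
Oc1ccc(CC=C)cc1-c1ccc(O)c(CC=C)c1	honokiol
COc1ccc(CCC(=O)c2ccc(O)cc2)c(OC)c1	loureirin_a
[Se]=C=NCCCCc1ccccc1	isc4
NCCc1c[nH]c2ccccc12	tryptamine
CNCCc1c[nH]c2ccc(O)cc12	n_methylserotonin
[NH3+]CCc1c[nH]c2ccc(O)cc12	serotonin_1plus
CNCC(O)c1ccc(O)c(OC)c1	metanephrine
O=CCc1c[nH]c2ccccc12	indol3ylacetaldehyde
NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1(F)F	gemcitabine
CNCCCN1c2ccccc2CCc2ccccc21	desipramine
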