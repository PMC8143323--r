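name	variant	smiles
ciprofloxacin	1	c1(=O)c2cc(F)c(N3CCNCC3)cc2n(C2CC2)cc1C(=O)O
ciprofloxacin	2	c1(C(O)=O)c(=O)c2c(cc(N3CCNCC3)c(F)c2)n(C2CC2)c1
ciprofloxacin	3	c12c(cc(F)c(N3CCNCC3)c1)c(=O)c(C(O)=O)cn2C1CC1
ciprofloxacin	4	c1c2c(cc(F)c1N1CCNCC1)c(=O)c(C(O)=O)cn2C1CC1
ciprofloxacin	5	n1(C2CC2)cc(C(O)=O)c(=O)c2cc(F)c(N3CCNCC3)cc12
enoxacin	1	C(n1c2nc(N3CCNCC3)c(F)cc2c(=O)c(C(=O)O)c1)C
enoxacin	2	C1CN(c2c(F)cc3c(=O)c(C(O)=O)cn(CC)c3n2)CCN1
enoxacin	3	O=c1c(C(O)=O)cn(CC)c2nc(N3CCNCC3)c(F)cc21
enoxacin	4	c1(=O)c(C(=O)O)cn(CC)c2c1cc(F)c(N1CCNCC1)n2
enoxacin	5	c1(N2CCNCC2)c(F)cc2c(=O)c(C(=O)O)cn(CC)c2n1
fleroxacin	1	Fc1c(N2CCN(C)CC2)c(F)c2n(CCF)cc(C(O)=O)c(=O)c2c1
fleroxacin	2	Fc1c(N2CCN(C)CC2)c(F)cc2c(=O)c(C(=O)O)cn(CCF)c21
fleroxacin	3	c1(F)c(N2CCN(C)CC2)c(F)c2c(c(=O)c(C(=O)O)cn2CCF)c1
fleroxacin	4	c1(F)cc2c(=O)c(C(O)=O)cn(CCF)c2c(F)c1N1CCN(C)CC1
fleroxacin	5	c1(N2CCN(C)CC2)c(F)c2c(cc1F)c(=O)c(C(O)=O)cn2CCF
lomefloxacin	1	C1N(c2c(F)cc3c(c2F)n(CC)cc(C(=O)O)c3=O)CC(C)NC1
lomefloxacin	2	CCn1c2c(c(=O)c(C(=O)O)c1)cc(F)c(N1CCNC(C)C1)c2F
lomefloxacin	3	c12cc(F)c(N3CC(C)NCC3)c(F)c1n(CC)cc(C(O)=O)c2=O
lomefloxacin	4	c12cc(F)c(N3CCNC(C)C3)c(F)c1n(CC)cc(C(O)=O)c2=O
lomefloxacin	5	c1n(CC)c2c(c(=O)c1C(O)=O)cc(F)c(N1CC(C)NCC1)c2F
norfloxacin	1	C(=O)(O)c1c(=O)c2c(cc(N3CCNCC3)c(F)c2)n(CC)c1
norfloxacin	2	C1CN(c2c(F)cc3c(n(CC)cc(C(=O)O)c3=O)c2)CCN1
norfloxacin	3	CCn1cc(C(=O)O)c(=O)c2cc(F)c(N3CCNCC3)cc12
norfloxacin	4	N1CCN(c2cc3n(CC)cc(C(O)=O)c(=O)c3cc2F)CC1
norfloxacin	5	c1(N2CCNCC2)cc2c(cc1F)c(=O)c(C(=O)O)cn2CC
ofloxacin	1	CC1n2c3c(c(=O)c(C(O)=O)c2)cc(F)c(N2CCN(C)CC2)c3OC1
ofloxacin	2	N1(c2c3c4n(cc(C(=O)O)c(=O)c4cc2F)C(C)CO3)CCN(C)CC1
ofloxacin	3	O=c1c(C(=O)O)cn2c3c1cc(F)c(N1CCN(C)CC1)c3OCC2C
ofloxacin	4	OC(=O)c1c(=O)c2c3n(c1)C(C)COc3c(N1CCN(C)CC1)c(F)c2
ofloxacin	5	c1(N2CCN(C)CC2)c2c3c(cc1F)c(=O)c(C(O)=O)cn3C(C)CO2
pefloxacin	1	C1CN(C)CCN1c1cc2c(cc1F)c(=O)c(C(=O)O)cn2CC
pefloxacin	2	c1(C(O)=O)c(=O)c2c(n(CC)c1)cc(N1CCN(C)CC1)c(F)c2
pefloxacin	3	c1(C(O)=O)c(=O)c2cc(F)c(N3CCN(C)CC3)cc2n(CC)c1
pefloxacin	4	c1(F)cc2c(=O)c(C(=O)O)cn(CC)c2cc1N1CCN(C)CC1
pefloxacin	5	c1c2n(CC)cc(C(=O)O)c(=O)c2cc(F)c1N1CCN(C)CC1
rufloxacin	1	C1CN(C)CCN1c1c(F)cc2c3n(cc(C(=O)O)c2=O)CCSc31
rufloxacin	2	C1CN(c2c(F)cc3c4n(cc(C(=O)O)c3=O)CCSc24)CCN1C
rufloxacin	3	C1CN(c2c(F)cc3c4n(cc(C(O)=O)c3=O)CCSc24)CCN1C
rufloxacin	4	N1(C)CCN(c2c(F)cc3c4n(cc(C(O)=O)c3=O)CCSc24)CC1
rufloxacin	5	OC(c1c(=O)c2c3n(c1)CCSc3c(N1CCN(C)CC1)c(F)c2)=O
levofloxacin	1	C1CN(C)CCN1c1c2c3n(cc(C(=O)O)c(=O)c3cc1F)[C@@H](C)CO2
levofloxacin	2	C1CN(c2c(F)cc3c4n(cc(C(=O)O)c3=O)[C@@H](C)COc24)CCN1C
levofloxacin	3	C1N(C)CCN(c2c(F)cc3c(=O)c(C(=O)O)cn4c3c2OC[C@@H]4C)C1
levofloxacin	4	OC(=O)c1c(=O)c2c3c(c(N4CCN(C)CC4)c(F)c2)OC[C@H](C)n3c1
levofloxacin	5	c12c3c(N4CCN(C)CC4)c(F)cc1c(=O)c(C(O)=O)cn2[C@@H](C)CO3
sparfloxacin	1	C1(C)CN(c2c(F)c3n(C4CC4)cc(C(=O)O)c(=O)c3c(N)c2F)CC(C)N1
sparfloxacin	2	C1(n2c3c(F)c(N4CC(C)NC(C)C4)c(F)c(N)c3c(=O)c(C(=O)O)c2)CC1
sparfloxacin	3	c1(=O)c2c(N)c(F)c(N3CC(C)NC(C)C3)c(F)c2n(C2CC2)cc1C(=O)O
sparfloxacin	4	c1(F)c(N)c2c(=O)c(C(=O)O)cn(C3CC3)c2c(F)c1N1CC(C)NC(C)C1
sparfloxacin	5	c1(N2CC(C)NC(C)C2)c(F)c2c(c(=O)c(C(O)=O)cn2C2CC2)c(N)c1F
tosufloxacin	1	C1(N)CN(c2c(F)cc3c(=O)c(C(O)=O)cn(-c4cc(F)ccc4F)c3n2)CC1
tosufloxacin	2	C1C(N)CCN1c1c(F)cc2c(=O)c(C(O)=O)cn(-c3cc(F)ccc3F)c2n1
tosufloxacin	3	C1CC(N)CN1c1c(F)cc2c(=O)c(C(=O)O)cn(-c3cc(F)ccc3F)c2n1
tosufloxacin	4	O=C(c1cn(-c2c(F)ccc(F)c2)c2nc(N3CC(N)CC3)c(F)cc2c1=O)O
tosufloxacin	5	c1(-n2c3nc(N4CCC(N)C4)c(F)cc3c(=O)c(C(O)=O)c2)cc(F)ccc1F
gatifloxacin	1	C(c1cn(C2CC2)c2c(OC)c(N3C(C)CNCC3)c(F)cc2c1=O)(O)=O
gatifloxacin	2	C1CNCC(C)N1c1c(F)cc2c(n(C3CC3)cc(C(=O)O)c2=O)c1OC
gatifloxacin	3	N1CC(C)N(c2c(OC)c3n(C4CC4)cc(C(=O)O)c(=O)c3cc2F)CC1
gatifloxacin	4	O(c1c2c(c(=O)c(C(O)=O)cn2C2CC2)cc(F)c1N1CCNCC1C)C
gatifloxacin	5	n1(C2CC2)c2c(c(=O)c(C(=O)O)c1)cc(F)c(N1CCNCC1C)c2OC
moxifloxacin	1	C1C(n2c3c(c(=O)c(C(=O)O)c2)cc(F)c(N2CC4NCCCC4C2)c3OC)C1
moxifloxacin	2	C1CNC2C(C1)CN(c1c(F)cc3c(=O)c(C(=O)O)cn(C4CC4)c3c1OC)C2
moxifloxacin	3	COc1c(N2CC3C(NCCC3)C2)c(F)cc2c1n(C1CC1)cc(C(=O)O)c2=O
moxifloxacin	4	c1(=O)c2cc(F)c(N3CC4C(NCCC4)C3)c(OC)c2n(C2CC2)cc1C(=O)O
moxifloxacin	5	c1c(C(=O)O)c(=O)c2cc(F)c(N3CC4C(NCCC4)C3)c(OC)c2n1C1CC1
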