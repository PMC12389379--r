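variant	preferred
emt	epithelial-mesenchymal transition
epithelial mesenchymal transition	epithelial-mesenchymal transition
epithelial–mesenchymal transition	epithelial-mesenchymal transition
5-fu	5-fluorouracil
5 fluorouracil	5-fluorouracil
5-fluouracil	5-fluorouracil
wnt/β-catenin	wnt/b-catenin
wnt/beta-catenin	wnt/b-catenin
wnt signaling	wnt/b-catenin
cell proliferation	proliferation
tumour proliferation	proliferation
cell migration	migration
cell invasion	invasion
programmed cell death	apoptosis
drug resistance	chemoresistance
chemo-resistance	chemoresistance
exosome	exosomes
cerna network	cerna
competing endogenous rna	cerna
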