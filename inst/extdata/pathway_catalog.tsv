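# Nutritional biosynthesis pathway catalog for planthopper endosymbiont
# consortia: the 10 essential amino acids, the non-essential amino acid
# cysteine, and the B vitamins riboflavin and biotin.  One row per
# enzymatic step; alternatives are comma-separated gene symbols
# (isozymes or alternative routes).  Methionine is catalogued as the
# terminal two-reaction route (metC, metE) from host-derived
# cystathionine, and arginine as the carAB-argFGH route from host-derived
# ornithine/glutamine, the host-complemented routes these reduced genomes
# retain.
pathway_id	display_name	class	step_index	alternatives
leucine	Leucine	EAA	1	leuA
leucine	Leucine	EAA	2	leuC
leucine	Leucine	EAA	3	leuD
leucine	Leucine	EAA	4	leuB
valine	Valine	EAA	1	ilvB,ilvH
valine	Valine	EAA	2	ilvC
valine	Valine	EAA	3	ilvD
valine	Valine	EAA	4	ilvE
isoleucine	Isoleucine	EAA	1	ilvA
isoleucine	Isoleucine	EAA	2	ilvB,ilvH
isoleucine	Isoleucine	EAA	3	ilvC
isoleucine	Isoleucine	EAA	4	ilvD
isoleucine	Isoleucine	EAA	5	ilvE
lysine	Lysine	EAA	1	dapA
lysine	Lysine	EAA	2	dapB
lysine	Lysine	EAA	3	dapC,argD
lysine	Lysine	EAA	4	dapD
lysine	Lysine	EAA	5	dapE
lysine	Lysine	EAA	6	dapF
lysine	Lysine	EAA	7	lysA
threonine	Threonine	EAA	1	thrA
threonine	Threonine	EAA	2	asd
threonine	Threonine	EAA	3	thrB
threonine	Threonine	EAA	4	thrC
methionine	Methionine	EAA	1	metC
methionine	Methionine	EAA	2	metE
histidine	Histidine	EAA	1	hisG
histidine	Histidine	EAA	2	hisI
histidine	Histidine	EAA	3	hisA
histidine	Histidine	EAA	4	hisF
histidine	Histidine	EAA	5	hisH
histidine	Histidine	EAA	6	hisB
histidine	Histidine	EAA	7	hisC
histidine	Histidine	EAA	8	hisN
histidine	Histidine	EAA	9	hisD
arginine	Arginine	EAA	1	carA
arginine	Arginine	EAA	2	carB
arginine	Arginine	EAA	3	argF,argI
arginine	Arginine	EAA	4	argG
arginine	Arginine	EAA	5	argH
phenylalanine	Phenylalanine (shikimate route)	EAA	1	aroF,aroG
phenylalanine	Phenylalanine (shikimate route)	EAA	2	aroB
phenylalanine	Phenylalanine (shikimate route)	EAA	3	aroD
phenylalanine	Phenylalanine (shikimate route)	EAA	4	aroE
phenylalanine	Phenylalanine (shikimate route)	EAA	5	aroK
phenylalanine	Phenylalanine (shikimate route)	EAA	6	aroA
phenylalanine	Phenylalanine (shikimate route)	EAA	7	aroC
phenylalanine	Phenylalanine (shikimate route)	EAA	8	pheA
tryptophan	Tryptophan	EAA	1	trpE
tryptophan	Tryptophan	EAA	2	trpD
tryptophan	Tryptophan	EAA	3	trpC
tryptophan	Tryptophan	EAA	4	trpA
tryptophan	Tryptophan	EAA	5	trpB
cysteine	Cysteine	non-essential AA	1	cysE
cysteine	Cysteine	non-essential AA	2	cysK
riboflavin	Riboflavin	B-vitamin	1	ribA
riboflavin	Riboflavin	B-vitamin	2	ribB
riboflavin	Riboflavin	B-vitamin	3	ribD
riboflavin	Riboflavin	B-vitamin	4	ribH
riboflavin	Riboflavin	B-vitamin	5	ribE
riboflavin	Riboflavin	B-vitamin	6	ribC
riboflavin	Riboflavin	B-vitamin	7	yigB
biotin	Biotin	B-vitamin	1	bioC
biotin	Biotin	B-vitamin	2	bioH
biotin	Biotin	B-vitamin	3	bioW
biotin	Biotin	B-vitamin	4	bioF
biotin	Biotin	B-vitamin	5	bioA
biotin	Biotin	B-vitamin	6	bioD
biotin	Biotin	B-vitamin	7	bioB
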