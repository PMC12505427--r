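# Curated presence of nutritional biosynthesis genes in the co-primary
# endosymbiont consortia of the planthoppers Cixius wagneri (CW) and
# Pentastiridius leporinus (PL): Karelsulcia, Vidania, Purcelliella and
# the reduced Gammaproteobacteria symbiont 'Ca. Mirabilia symbiotica'.
# status: present | present_split (gene split in two by an internal stop
# codon but scored as retained).  source: reported = gene explicitly
# named for these symbionts in the primary literature; curated =
# transcribed from the published pathway repertoire.
genome	symbiont	host	gene	status	source
Karelsulcia_CW	Karelsulcia	C_wagneri	leuA	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	leuB	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	leuC	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	leuD	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	ilvB	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	ilvH	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	ilvC	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	ilvD	present	curated
Karelsulcia_CW	Karelsulcia	C_wagneri	ilvE	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	leuA	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	leuB	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	leuC	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	leuD	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	ilvB	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	ilvH	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	ilvC	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	ilvD	present	curated
Karelsulcia_PL	Karelsulcia	P_leporinus	ilvE	present	curated
Vidania_CW	Vidania	C_wagneri	carA	present	reported
Vidania_CW	Vidania	C_wagneri	carB	present	reported
Vidania_CW	Vidania	C_wagneri	argF	present	reported
Vidania_CW	Vidania	C_wagneri	argG	present	reported
Vidania_CW	Vidania	C_wagneri	argH	present	reported
Vidania_CW	Vidania	C_wagneri	hisG	present	curated
Vidania_CW	Vidania	C_wagneri	hisI	present	curated
Vidania_CW	Vidania	C_wagneri	hisA	present	curated
Vidania_CW	Vidania	C_wagneri	hisF	present	curated
Vidania_CW	Vidania	C_wagneri	hisH	present	curated
Vidania_CW	Vidania	C_wagneri	hisB	present	curated
Vidania_CW	Vidania	C_wagneri	hisC	present	curated
Vidania_CW	Vidania	C_wagneri	hisD	present	curated
Vidania_CW	Vidania	C_wagneri	dapA	present	curated
Vidania_CW	Vidania	C_wagneri	dapB	present	curated
Vidania_CW	Vidania	C_wagneri	dapC	present	reported
Vidania_CW	Vidania	C_wagneri	argD	present	reported
Vidania_CW	Vidania	C_wagneri	dapD	present	curated
Vidania_CW	Vidania	C_wagneri	dapE	present	curated
Vidania_CW	Vidania	C_wagneri	dapF	present	curated
Vidania_CW	Vidania	C_wagneri	lysA	present	curated
Vidania_CW	Vidania	C_wagneri	metC	present	reported
Vidania_CW	Vidania	C_wagneri	metE	present	reported
Vidania_CW	Vidania	C_wagneri	thrA	present	curated
Vidania_CW	Vidania	C_wagneri	asd	present	curated
Vidania_CW	Vidania	C_wagneri	thrB	present	curated
Vidania_CW	Vidania	C_wagneri	thrC	present	curated
Vidania_CW	Vidania	C_wagneri	trpE	present	curated
Vidania_CW	Vidania	C_wagneri	trpD	present	curated
Vidania_CW	Vidania	C_wagneri	trpC	present	curated
Vidania_CW	Vidania	C_wagneri	trpA	present	curated
Vidania_CW	Vidania	C_wagneri	trpB	present	curated
Vidania_CW	Vidania	C_wagneri	aroF	present	reported
Vidania_CW	Vidania	C_wagneri	aroG	present	reported
Vidania_CW	Vidania	C_wagneri	aroB	present	curated
Vidania_CW	Vidania	C_wagneri	aroD	present	curated
Vidania_CW	Vidania	C_wagneri	aroK	present	curated
Vidania_CW	Vidania	C_wagneri	aroA	present	curated
Vidania_CW	Vidania	C_wagneri	aroC	present	curated
Vidania_CW	Vidania	C_wagneri	pheA	present	curated
Vidania_PL	Vidania	P_leporinus	carA	present	reported
Vidania_PL	Vidania	P_leporinus	carB	present	reported
Vidania_PL	Vidania	P_leporinus	argF	present	reported
Vidania_PL	Vidania	P_leporinus	argG	present	reported
Vidania_PL	Vidania	P_leporinus	argH	present	reported
Vidania_PL	Vidania	P_leporinus	hisG	present	curated
Vidania_PL	Vidania	P_leporinus	hisI	present	curated
Vidania_PL	Vidania	P_leporinus	hisA	present	curated
Vidania_PL	Vidania	P_leporinus	hisF	present	curated
Vidania_PL	Vidania	P_leporinus	hisH	present	curated
Vidania_PL	Vidania	P_leporinus	hisB	present	curated
Vidania_PL	Vidania	P_leporinus	hisC	present	curated
Vidania_PL	Vidania	P_leporinus	hisD	present	curated
Vidania_PL	Vidania	P_leporinus	dapA	present	curated
Vidania_PL	Vidania	P_leporinus	dapB	present	curated
Vidania_PL	Vidania	P_leporinus	dapC	present	reported
Vidania_PL	Vidania	P_leporinus	argD	present	reported
Vidania_PL	Vidania	P_leporinus	dapD	present	curated
Vidania_PL	Vidania	P_leporinus	dapE	present	curated
Vidania_PL	Vidania	P_leporinus	dapF	present	curated
Vidania_PL	Vidania	P_leporinus	lysA	present	curated
Vidania_PL	Vidania	P_leporinus	metC	present	reported
Vidania_PL	Vidania	P_leporinus	metE	present	reported
Vidania_PL	Vidania	P_leporinus	thrA	present	curated
Vidania_PL	Vidania	P_leporinus	asd	present	curated
Vidania_PL	Vidania	P_leporinus	thrB	present	curated
Vidania_PL	Vidania	P_leporinus	thrC	present	curated
Vidania_PL	Vidania	P_leporinus	trpE	present	curated
Vidania_PL	Vidania	P_leporinus	trpD	present	curated
Vidania_PL	Vidania	P_leporinus	trpC	present	curated
Vidania_PL	Vidania	P_leporinus	trpA	present	curated
Vidania_PL	Vidania	P_leporinus	trpB	present	curated
Vidania_PL	Vidania	P_leporinus	aroF	present	reported
Vidania_PL	Vidania	P_leporinus	aroG	present	reported
Vidania_PL	Vidania	P_leporinus	aroB	present	curated
Vidania_PL	Vidania	P_leporinus	aroD	present	curated
Vidania_PL	Vidania	P_leporinus	aroE	present	reported
Vidania_PL	Vidania	P_leporinus	aroK	present	curated
Vidania_PL	Vidania	P_leporinus	aroA	present	curated
Vidania_PL	Vidania	P_leporinus	aroC	present	curated
Vidania_PL	Vidania	P_leporinus	pheA	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	cysE	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	cysK	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribA	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribB	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribD	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribH	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribE	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	ribC	present	curated
Purcelliella_PL	Purcelliella	P_leporinus	bioB	present	reported
Mirabilia_CW	Mirabilia	C_wagneri	cysE	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	cysK	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	ribA	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	ribB	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	ribD	present_split	reported
Mirabilia_CW	Mirabilia	C_wagneri	ribH	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	ribE	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	ribC	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	bioC	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	bioF	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	bioA	present_split	reported
Mirabilia_CW	Mirabilia	C_wagneri	bioD	present	curated
Mirabilia_CW	Mirabilia	C_wagneri	bioB	present	reported
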