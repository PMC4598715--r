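name	class	formula	side_smiles	piece_override	n_oh	n_nh2	description
gly	amino_acid	C2H5NO2			0	0	glycine
ala	amino_acid	C3H7NO2	C		0	0	alanine
ser	amino_acid	C3H7NO3	C{OH}		1	0	serine
pro	amino_acid	C5H9NO2		N1CCCC1C(=O)	0	0	proline
val	amino_acid	C5H11NO2	C(C)C		0	0	valine
thr	amino_acid	C4H9NO3	C({OH})C		1	0	threonine
cys	amino_acid	C3H7NO2S	CS		0	0	cysteine
leu	amino_acid	C6H13NO2	CC(C)C		0	0	leucine
ile	amino_acid	C6H13NO2	C(C)CC		0	0	isoleucine
asn	amino_acid	C4H8N2O3	CC(N)=O		0	0	asparagine
asp	amino_acid	C4H7NO4	CC(O)=O		0	0	aspartate
gln	amino_acid	C5H10N2O3	CCC(N)=O		0	0	glutamine
glu	amino_acid	C5H9NO4	CCC(O)=O		0	0	glutamate
lys	amino_acid	C6H14N2O2	CCCC{NH2}		0	1	lysine
met	amino_acid	C5H11NO2S	CCSC		0	0	methionine
his	amino_acid	C6H9N3O2	Cc1c[nH]cn1		0	0	histidine
phe	amino_acid	C9H11NO2	Cc1ccccc1		0	0	phenylalanine
arg	amino_acid	C6H14N4O2	CCCNC(N)=N		0	0	arginine
tyr	amino_acid	C9H11NO3	Cc1ccc({OH})cc1		1	0	tyrosine
trp	amino_acid	C11H12N2O2	Cc1c[nH]c2ccccc12		0	0	tryptophan
orn	amino_acid	C5H12N2O2	CCC{NH2}		0	1	ornithine
dab	amino_acid	C4H10N2O2	CC{NH2}		0	1	2,4-diaminobutyrate
hse	amino_acid	C4H9NO3	CC{OH}		1	0	homoserine
bohasp	amino_acid	C4H7NO5	C({OH})C(O)=O		1	0	beta-hydroxyaspartate
clthr	amino_acid	C4H8ClNO3	C({OH})CCl		1	0	4-chlorothreonine
dhb	amino_acid	C4H7NO2		NC(=CC)C(=O)	0	0	dehydrobutyrine (dehydroaminobutyrate)
orn_noh	amino_acid	C5H12N2O3	CCCNO		0	0	N5-hydroxyornithine
orn_fo	amino_acid	C6H12N2O3	CCCNC=O		0	0	N5-formylornithine
orn_ac	amino_acid	C7H14N2O3	CCCNC(C)=O		0	0	N5-acetylornithine
orn_noh_fo	amino_acid	C6H12N2O4	CCCN(O)C=O		0	0	N5-hydroxy-N5-formylornithine
orn_noh_ac	amino_acid	C7H14N2O4	CCCN(O)C(C)=O		0	0	N5-hydroxy-N5-acetylornithine
mal	ketide_unit	C2H4O2			0	0	malonate extender (acetate unit, beta-keto base state)
mmal	ketide_unit	C3H6O2			0	0	methylmalonate extender (propionate unit, beta-keto base state)
acetyl	fatty_acyl	C2H4O2		CC(=O)	0	0	acetyl starter
prop	fatty_acyl	C3H6O2		CCC(=O)	0	0	propionyl starter
c8	fatty_acyl	C8H16O2		CCCCCCCC(=O)	0	0	octanoyl
c8_oh	fatty_acyl	C8H16O3		CCCCCC({OH})CC(=O)	1	0	3-hydroxyoctanoyl
c8_ohoh	fatty_acyl	C8H16O4		CCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxyoctanoyl
c10	fatty_acyl	C10H20O2		CCCCCCCCCC(=O)	0	0	decanoyl
c10_oh	fatty_acyl	C10H20O3		CCCCCCCC({OH})CC(=O)	1	0	3-hydroxydecanoyl
c10_ohoh	fatty_acyl	C10H20O4		CCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxydecanoyl
c12	fatty_acyl	C12H24O2		CCCCCCCCCCCC(=O)	0	0	dodecanoyl
c12_oh	fatty_acyl	C12H24O3		CCCCCCCCCC({OH})CC(=O)	1	0	3-hydroxydodecanoyl
c12_ohoh	fatty_acyl	C12H24O4		CCCCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxydodecanoyl
c13_oh	fatty_acyl	C13H26O3		CCCCCCCCCCC({OH})CC(=O)	1	0	3-hydroxytridecanoyl
c13_ohoh	fatty_acyl	C13H26O4		CCCCCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxytridecanoyl
c14	fatty_acyl	C14H28O2		CCCCCCCCCCCCCC(=O)	0	0	tetradecanoyl
c14_oh	fatty_acyl	C14H28O3		CCCCCCCCCCCC({OH})CC(=O)	1	0	3-hydroxytetradecanoyl (beta-hydroxymyristoyl)
c14_ohoh	fatty_acyl	C14H28O4		CCCCCCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxytetradecanoyl
c15_oh	fatty_acyl	C15H30O3		CCCCCCCCCCCCC({OH})CC(=O)	1	0	3-hydroxypentadecanoyl
c15_ohoh	fatty_acyl	C15H30O4		CCCCCCCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxypentadecanoyl
c16	fatty_acyl	C16H32O2		CCCCCCCCCCCCCCCC(=O)	0	0	hexadecanoyl
c16_oh	fatty_acyl	C16H32O3		CCCCCCCCCCCCCC({OH})CC(=O)	1	0	3-hydroxyhexadecanoyl
c16_ohoh	fatty_acyl	C16H32O4		CCCCCCCCCCCCC({OH})C({OH})CC(=O)	2	0	3,4-dihydroxyhexadecanoyl
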