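name	sugar_class	formula	attach_smiles	gene_families	description
olivose	deoxyhexose	C6H12O4	C1OC(C)C(O)C(O)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_ketoreductase;4_ketoreductase	D-olivose (2,6-dideoxyhexose)
oliose	deoxyhexose	C6H12O4	C1OC(C)C(O)C(O)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_ketoreductase;4_ketoreductase;3_epimerase	D-oliose (2,6-dideoxyhexose, 3-epimer)
digitoxose	deoxyhexose	C6H12O4	C1OC(C)C(O)C(O)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_ketoreductase;4_ketoreductase;5_epimerase	D-digitoxose (2,6-dideoxyhexose)
amicetose	deoxyhexose	C6H12O3	C1OC(C)C(O)CC1	ntd_synthase;46_dehydratase;23_dehydratase;3_dehydratase;4_ketoreductase	D-amicetose (2,3,6-trideoxyhexose)
rhamnose	deoxyhexose	C6H12O5	C1OC(C)C(O)C(O)C1O	ntd_synthase;46_dehydratase;5_epimerase;4_ketoreductase	L-rhamnose (6-deoxyhexose)
mycarose	deoxyhexose	C7H14O4	C1OC(C)C(O)C(C)(O)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_c_methyltransferase;4_ketoreductase	D-mycarose (2,6-dideoxy-3-C-methylhexose)
oleandrose	deoxyhexose	C7H14O4	C1OC(C)C(O)C(OC)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_ketoreductase;4_ketoreductase;3_o_methyltransferase	L-oleandrose (2,6-dideoxy-3-O-methylhexose)
chalcose	deoxyhexose	C7H14O4	C1OC(C)CC(OC)C1O	ntd_synthase;46_dehydratase;34_isomerase;3_ketoreductase;3_o_methyltransferase	D-chalcose (4,6-dideoxy-3-O-methylhexose)
desosamine	deoxyhexose	C8H17NO3	C1OC(C)CC(N(C)C)C1O	ntd_synthase;46_dehydratase;34_isomerase;3_aminotransferase;n_dimethyltransferase	D-desosamine (3-dimethylamino-3,4,6-trideoxyhexose)
mycaminose	deoxyhexose	C8H17NO4	C1OC(C)C(O)C(N(C)C)C1O	ntd_synthase;46_dehydratase;34_isomerase;3_aminotransferase;n_dimethyltransferase;4_ketoreductase	D-mycaminose (3-dimethylamino-3,6-dideoxyhexose)
ravidosamine	deoxyhexose	C8H17NO4	C1OC(C)C(O)C(N(C)C)C1O	ntd_synthase;46_dehydratase;34_isomerase;3_aminotransferase;n_dimethyltransferase;4_ketoreductase	D-ravidosamine (diastereomer of mycaminose; identical pathway families)
angolosamine	deoxyhexose	C8H17NO3	C1OC(C)C(O)C(N(C)C)C1	ntd_synthase;46_dehydratase;23_dehydratase;3_aminotransferase;n_dimethyltransferase	D-angolosamine (3-dimethylamino-2,3,6-trideoxyhexose)
forosamine	deoxyhexose	C8H17NO2	C1OC(C)C(N(C)C)CC1	ntd_synthase;46_dehydratase;23_dehydratase;3_dehydratase;4_aminotransferase;n_dimethyltransferase	D-forosamine (4-dimethylamino-2,3,4,6-tetradeoxyhexose)
xylose	pentose	C5H10O5	C1OCC(O)C(O)C1O	udpg_dehydrogenase;udpg_decarboxylase	D-xylose-type pentose (UDP pathway)
madurose	pentose	C6H12O5	C1OCC(O)C(C)(O)C1O	udpg_dehydrogenase;udpg_decarboxylase;3_c_methyltransferase;3_epimerase	madurose-type 3-C-methylpentose (UDP pathway)
glucose	hexose	C6H12O6	C1OC(CO)C(O)C(O)C1O		D-glucose (hexose; assigned from glycosyltransferase homology)
mannose	hexose	C6H12O6	C1OC(CO)C(O)C(O)C1O		D-mannose (hexose; assigned from glycosyltransferase homology)
gulose	hexose	C6H12O6	C1OC(CO)C(O)C(O)C1O		D-gulose (hexose; assigned from glycosyltransferase homology)
n_acetylglucosamine	hexose	C8H15NO6	C1OC(CO)C(O)C(O)C1NC(C)=O		N-acetylglucosamine (hexose; assigned from glycosyltransferase homology)
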