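# Thanamycin (Pseudomonas fluorescens) combinatorialization:
# syringomycin-type lipodepsipeptide, macrocyclized on the conserved serine
# hydroxyl; position 2 in {diaminobutyrate, ornithine, arginine}; position 3
# in {aspartate, asparagine}; position 4 in {serine, threonine/homoserine
# (isomers; homoserine shown)}; N-acyl chain C12-C16 with one or two
# hydroxyls. 3 x 2 x 2 x 10 = 120 structures.
library thanamycin
scaffold thana: c12_oh ser dab asn ser gly phe dhb bohasp clthr
cyclization: lactone@2
axis pos2: 3=dab | 3=orn | 3=arg
axis pos3: 4=asp | 4=asn
axis pos4: 5=ser | 5=hse
axis acyl: 1=c12_oh | 1=c12_ohoh | 1=c13_oh | 1=c13_ohoh | 1=c14_oh | 1=c14_ohoh | 1=c15_oh | 1=c15_ohoh | 1=c16_oh | 1=c16_ohoh
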