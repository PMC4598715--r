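# WS9326 (Streptomyces calvus) combinatorialization: lipopeptide with an
# initial acylating condensation domain; four base scaffolds from the two
# trans-acting adenylation-thiolation didomain placements (Asn/Thr position
# swaps); N-acyl axis C8/C10/C12; serine/threonine, valine/leucine-isoleucine
# and phenylalanine/tyrosine interchangeable at the positions bearing them.
# 4 x 3 x 2^6 = 768 structures.
library ws9326
scaffold swap_a: c10 thr ser val leu phe tyr asn thr gly
scaffold swap_b: c10 thr ser val leu phe tyr thr asn gly
scaffold swap_c: c10 thr ser val leu phe tyr asn gly thr
scaffold swap_d: c10 thr ser val leu phe tyr thr gly asn
cyclization: linear
axis acyl: 1=c8 | 1=c10 | 1=c12
axis pos1: 2=thr | 2=ser
axis pos2: 3=ser | 3=thr
axis pos3: 4=val | 4=leu
axis pos4: 5=leu | 5=ile
axis pos5: 6=phe | 6=tyr
axis pos6: 7=tyr | 7=phe
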