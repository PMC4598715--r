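# Variobactin (Variovorax paradoxus P4B): lipopeptide/lipodepsipeptide;
# linear and macrocycle forms; Ser/Thr interchange; malonate/methylmalonate;
# predicted N-hydroxyornithine N-formylated, N-acetylated or not further
# modified (or the unhydroxylated amine). 2 x 2 x 2 x 4 = 32 structures.
library variobactin
scaffold vario: c12 ser orn_noh mal(KR) thr bohasp gly
cyclization: linear | lactone@2
axis serthr: 5=thr | 5=ser
axis ketide: 4=mal(KR) | 4=mmal(KR)
axis orn: 3=orn_noh | 3=orn_noh_fo | 3=orn_noh_ac | 3=orn
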