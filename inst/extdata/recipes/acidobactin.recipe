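# Acidobactin (Acidovorax citrulli AAC00-1) combinatorialization:
# delftibactin-like NRPS-PKS hybrid; linear and macrocycle forms; serines
# and threonines interchangeable; the ketide unit malonate or
# methylmalonate; ornithine side chains free, N-hydroxylated, N-formylated,
# N-acetylated or combinations. 2 x 2 x 2 x 6 x 6 x 2 = 576 structures.
library acidobactin
scaffold acido: c8 thr orn mal(KR) ser thr bohasp orn
cyclization: linear | lactone@2
axis serthr1: 5=ser | 5=thr
axis serthr2: 6=thr | 6=ser
axis orn1: 3=orn | 3=orn_noh | 3=orn_fo | 3=orn_ac | 3=orn_noh_fo | 3=orn_noh_ac
axis orn2: 8=orn | 8=orn_noh | 8=orn_fo | 8=orn_ac | 8=orn_noh_fo | 8=orn_noh_ac
axis ketide: 4=mal(KR) | 4=mmal(KR)
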