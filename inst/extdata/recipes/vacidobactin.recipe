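# Vacidobactin (Variovorax paradoxus S110): acidobactin-like scaffold with
# a resolved fatty acyl-AMP ligase starter; combinatorialized identically
# (linear and depsipeptide macrocycle forms, Ser/Thr interchange, malonate/
# methylmalonate, ornithine side-chain states). 2 x 2 x 2 x 6 x 6 x 2 = 576.
library vacidobactin
scaffold vacido: c8 thr orn mmal(KR) ser thr bohasp orn
cyclization: linear | lactone@2
axis serthr1: 5=ser | 5=thr
axis serthr2: 6=thr | 6=ser
axis orn1: 3=orn | 3=orn_noh | 3=orn_fo | 3=orn_ac | 3=orn_noh_fo | 3=orn_noh_ac
axis orn2: 8=orn | 8=orn_noh | 8=orn_fo | 8=orn_ac | 8=orn_noh_fo | 8=orn_noh_ac
axis ketide: 4=mal(KR) | 4=mmal(KR)
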