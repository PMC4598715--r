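# Potensimicin (Nocardiopsis potens DSM 45234): narbonolide-type polyketide
# with two predicted deoxysugars (angolosamine; mycaminose or its
# diastereomer ravidosamine). The backbone is either left linear (both
# ketoreductase hydroxyls free: glycosylated with both sugars, either alone,
# or neither) or macrocyclized on the distal hydroxyl (lone remaining free
# hydroxyl: either sugar or bare). All methylmalonates interchangeable with
# malonate, encoded as single-position swaps (none or one of the five
# extender units). (4 x 6) + (3 x 6) = 42 structures.
library potensimicin_linear
scaffold potens: prop mmal(KR) mmal mmal(KR) mmal mmal(KR,DH)
cyclization: linear
axis sugars: glyco:2=angolosamine+glyco:4=mycaminose | glyco:2=angolosamine | glyco:2=mycaminose | none
axis mm: none | 2=mal(KR) | 3=mal | 4=mal(KR) | 5=mal | 6=mal(KR,DH)
library potensimicin_macro
scaffold potens: prop mmal(KR) mmal mmal(KR) mmal mmal(KR,DH)
cyclization: lactone@2
axis sugars: glyco:4=angolosamine | glyco:4=mycaminose | none
axis mm: none | 2=mal(KR) | 3=mal | 4=mal(KR) | 5=mal | 6=mal(KR,DH)
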