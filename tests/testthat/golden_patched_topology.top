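[ moleculetype ]
; name  nrexcl
Protein 1

[ atoms ]
;  nr type resnr residue atom cgnr charge mass
   1  CA     1  ALA   CA     1  0.0  110.0
   2  CA     2  ALA   CA     2  0.0  110.0
   3  CA     3  ALA   CA     3  0.0  110.0
   4  CA     4  ALA   CA     4  0.0  110.0
   5  CA     5  ALA   CA     5  0.0  110.0
   6  CA     6  ALA   CA     6  0.0  110.0
   7  CA     7  ALA   CA     7  0.0  110.0
   8  CA     8  ALA   CA     8  0.0  110.0

[ bonds ]
;  ai  aj funct
   1    2 1 0.38 8000
   2    3 1 0.38 8000
   3    4 1 0.38 8000
   4    5 1 0.38 8000
   5    6 1 0.38 8000
   6    7 1 0.38 8000
   7    8 1 0.38 8000

     1      5     9     1    10.000000
     2      8     9     1    10.000000
[ system ]
Toy
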