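paired:
- - sep_L1
  - sep_R1
- - sep_L2
  - sep_R2
- - sep_L3
  - sep_R3
- - sep_L4
  - sep_R4
- - sep_L5
  - sep_R5
- - sep_L6
  - sep_R6
- - sep_L7
  - sep_R7
- - sep_L8
  - sep_R8
- - pet_L1
  - pet_R1
- - pet_L2
  - pet_R2
- - pet_L3
  - pet_R3
- - pet_L4
  - pet_R4
- - pet_L5
  - pet_R5
- - lab_L1
  - lab_R1
- - lab_L2
  - lab_R2
- - lab_L3
  - lab_R3
- - col_L1
  - col_R1
- - col_L2
  - col_R2
- - col_L3
  - col_R3
- - col_L4
  - col_R4
- - col_L5
  - col_R5
midline:
- sep_m1
- sep_m2
- lab_m1
- lab_m2
- lab_m3
- lab_m4
- col_m1
- col_m2
- foot_m1
- foot_m2
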