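"landmark","organ"
"sep_m1","sepal"
"sep_m2","sepal"
"sep_L1","sepal"
"sep_L2","sepal"
"sep_L3","sepal"
"sep_L4","sepal"
"sep_L5","sepal"
"sep_L6","sepal"
"sep_L7","sepal"
"sep_L8","sepal"
"sep_R1","sepal"
"sep_R2","sepal"
"sep_R3","sepal"
"sep_R4","sepal"
"sep_R5","sepal"
"sep_R6","sepal"
"sep_R7","sepal"
"sep_R8","sepal"
"pet_L1","petal"
"pet_L2","petal"
"pet_L3","petal"
"pet_L4","petal"
"pet_L5","petal"
"pet_R1","petal"
"pet_R2","petal"
"pet_R3","petal"
"pet_R4","petal"
"pet_R5","petal"
"lab_m1","labellum"
"lab_m2","labellum"
"lab_m3","labellum"
"lab_m4","labellum"
"lab_L1","labellum"
"lab_L2","labellum"
"lab_L3","labellum"
"lab_R1","labellum"
"lab_R2","labellum"
"lab_R3","labellum"
"col_m1","column"
"col_m2","column"
"col_L1","column"
"col_L2","column"
"col_L3","column"
"col_L4","column"
"col_L5","column"
"col_R1","column"
"col_R2","column"
"col_R3","column"
"col_R4","column"
"col_R5","column"
"foot_m1","column_foot"
"foot_m2","column_foot"
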