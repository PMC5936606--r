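outcome,category,n
gestational_age,preterm,244
gestational_age,term,4149
gestational_age,postterm,22
birth_weight,LBW,213
birth_weight,normal,4078
birth_weight,macrosomia,124
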