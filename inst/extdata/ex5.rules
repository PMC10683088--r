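# subsumption: S06 restates S05 with extra premise atoms; S07-S09 specialise
# S05 through sub-properties of hasFood
S05: hasFood(x,y), hasIngredient(y,z) -> eats(x,z)
S06: Patient(x), Food(y), hasFood(x,y), hasIngredient(y,z) -> eats(x,z)
S07: hasLunch(x,y), hasIngredient(y,z) -> eats(x,z)
S08: hasBreakfast(x,y), hasIngredient(y,z) -> eats(x,z)
S09: hasDiner(x,y), hasIngredient(y,z) -> eats(x,z)
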