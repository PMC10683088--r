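# four mutually equivalent phrasings of "a patient eats the ingredients of
# their food": identical atoms reordered (S02), a sub-property in the premise
# (S03), a sub-property in the conclusion (S04)
S01: Patient(x), hasFood(x,y), hasIngredient(y,z) -> eats(x,z)
S02: Patient(x), hasIngredient(y,z), hasFood(x,y) -> eats(x,z)
S03: Patient(x), hasLunch(x,y), hasIngredient(y,z) -> eats(x,z)
S04: Patient(x), hasFood(x,y), hasIngredient(y,z) -> gets(x,z)
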