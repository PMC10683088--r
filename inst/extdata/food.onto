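# nutrition schema: patients, meals and what they are made of
class Person
class Patient < Person
class Edible
class Food < Edible
class Lunch < Food
class Breakfast < Food
class Diner < Food
class Ingredient < Edible
objprop hasFood domain Patient range Food
objprop hasLunch domain Patient range Lunch < hasFood
objprop hasBreakfast domain Patient range Breakfast < hasFood
objprop hasDiner domain Patient range Diner < hasFood
objprop hasIngredient domain Food range Ingredient
objprop contains domain Food range Ingredient equiv hasIngredient
# eats is the parent property of gets in the property tree
objprop eats domain Patient range Food
objprop gets domain Patient range Edible < eats
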