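# meal-planning schema for the expert-review conflict case
class Food
class MealLevel
dataprop has-glycemic-index domain Food range decimal[0..110]
objprop has-meal-level domain Food range MealLevel
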