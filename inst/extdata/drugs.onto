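# drug categorisation schema for the fake-cycle case
class Drug
class Category
objprop hasCategory domain Drug range Category
objprop hasEquivalent domain Drug range Drug
objprop includes domain Category range Drug
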