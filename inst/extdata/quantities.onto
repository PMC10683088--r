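# opposite comparison properties declared as inverses
class Quantity
class Flagged
objprop isGreaterThan domain Quantity range Quantity inverse isLessThan
objprop isLessThan domain Quantity range Quantity
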