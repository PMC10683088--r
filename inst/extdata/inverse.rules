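# x cannot be both greater and less than y once the properties are inverses
V01: Quantity(x), Quantity(y), isGreaterThan(x,y), isLessThan(x,y) -> Flagged(x)
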