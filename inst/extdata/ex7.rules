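# a dependency-graph cycle over drug categories that does not loop on
# instances (the derivations close after one lap)
St01: Drug(d1), hasCategory(d1,c), hasEquivalent(d1,d2) -> hasCategory(d2,c)
St02: hasCategory(d2,c) -> includes(c,d2)
St03: Drug(d2), includes(c,d2), Drug(d3), hasEquivalent(d3,d2) -> hasCategory(d3,c)
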