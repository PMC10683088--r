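# >= 21 and > 20 describe the same integer set but different builtin spellings
R08: PatientProfile(p), hasSmoking(p,s), hasDailyCigarettes(s,d), greaterThanOrEqual(d,21) -> vectorItemSmoking(p,3)
R08b: PatientProfile(p), hasSmoking(p,s), hasDailyCigarettes(s,d), moreThan(d,20) -> vectorItemSmoking(p,3)
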