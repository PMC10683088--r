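# transitivity: S12 composes the diagnosis S10 with the prescription S11
S10: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType2(x)
S11: DiabetesType2(x) -> gets(x,Metformin)
S12: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> gets(x,Metformin)
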