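# conflict corpus: S10/S14 strong (same premise, disjoint diagnoses),
# S11/S15 probable (disjoint premises, same prescription), S10/S13 probable
# (complementary thresholds, same diagnosis)
S10: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType2(x)
S11: DiabetesType2(x) -> gets(x,Metformin)
S13: Person(x), hasFBST(x,i), equalOrLessThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType2(x)
S14: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType1(x)
S15: DiabetesType1(x) -> gets(x,Metformin)
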