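# inaccessible: the premise conjoins disjoint diagnoses
S30: DiabetesType1(x), DiabetesType2(x) -> gets(x,Metformin)
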