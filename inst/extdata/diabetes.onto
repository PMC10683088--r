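# diabetes triage schema
class Person
class Patient < Person
class DiabetesType1 < Person
class DiabetesType2 < Person
class DiabetesType1 disjoint DiabetesType2
class Drug
class HypertensiveEmergency < Person
dataprop hasFBST domain Person range decimal[0..10]
dataprop hasGI domain Person range decimal[0..10]
dataprop hasSymptomsT2 domain Person range {True,False}
dataprop systolicArterialPressure domain Person range decimal[0..300]
dataprop diastolicBloodPressure domain Person range decimal[0..300]
dataprop age domain Person range integer[0..150]
objprop gets domain Person range Drug
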