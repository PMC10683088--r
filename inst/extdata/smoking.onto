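# smoking-score schema for the spelled-differently-thresholds case
class PatientProfile
class Smoking
objprop hasSmoking domain PatientProfile range Smoking
dataprop hasDailyCigarettes domain Smoking range integer[0..200]
dataprop vectorItemSmoking domain PatientProfile range integer[0..10]
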