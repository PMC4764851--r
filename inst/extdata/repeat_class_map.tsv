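raw	class
SINE	SINE
SINE?	SINE
LINE	LINE
LINE?	LINE
LTR	LTR
LTR?	LTR
DNA	DNA
DNA?	DNA
RC	DNA
Retroelement	Retroelement
Retro	Retroelement
Unknown	Unclassified
Unclassified	Unclassified
Unspecified	Unclassified
ARTEFACT	Unclassified
snRNA	SmallRNA
tRNA	SmallRNA
rRNA	SmallRNA
scRNA	SmallRNA
srpRNA	SmallRNA
SmallRNA	SmallRNA
Satellite	Satellite
Simple_repeat	SimpleRepeat
SimpleRepeat	SimpleRepeat
Low_complexity	LowComplexity
LowComplexity	LowComplexity
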