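# misspelling <TAB> corrected form
pravastain	pravastatin
obeise	obese
diabetis	diabetes
hypertention	hypertension
cholestrol	cholesterol
metforman	metformin
lisinipril	lisinopril
asprin	aspirin
atorvastatine	atorvastatin
hyperlipidemea	hyperlipidemia
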