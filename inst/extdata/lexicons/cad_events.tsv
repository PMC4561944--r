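# CAD clinical phrase <TAB> indicator (event / test result / symptom)
myocardial infarction	event
heart attack	event
angioplasty	event
stent placement	event
cabg	event
coronary bypass	event
bypass surgery	event
stress test	test result
cardiac catheterization	test result
coronary angiography	test result
abnormal ekg	test result
chest pain	symptom
angina	symptom
exertional chest pressure	symptom
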