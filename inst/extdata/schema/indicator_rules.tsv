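# Declarative indicator-assignment rule ledger.
# source <TAB> key <TAB> risk factor <TAB> indicator
# source: provenance of the recognized item (disease dictionary hit, CAD
# clinical-phrase hit, thresholded lab value, medication dictionary hit).
disease	CAD	CAD	mention
disease	DIABETES	DIABETES	mention
disease	HYPERLIPIDEMIA	HYPERLIPIDEMIA	mention
disease	HYPERTENSION	HYPERTENSION	mention
disease	OBESITY	OBESITY	mention
cad_event	event	CAD	event
cad_event	test result	CAD	test result
cad_event	symptom	CAD	symptom
lab	BP	HYPERTENSION	high blood pressure
lab	A1C	DIABETES	high A1c
lab	GLUCOSE	DIABETES	high glucose
lab	TOTAL_CHOL	HYPERLIPIDEMIA	high cholesterol
lab	LDL	HYPERLIPIDEMIA	high LDL
lab	BMI	OBESITY	BMI
medication	ACE inhibitors	MEDICATION	ACE inhibitors
medication	ACE inhibitors ARBs	MEDICATION	ACE inhibitors ARBs
medication	amylin	MEDICATION	amylin
medication	antidiabetes medications	MEDICATION	antidiabetes medications
medication	aspirin	MEDICATION	aspirin
medication	beta-blockers	MEDICATION	beta-blockers
medication	calcium-channel blockers	MEDICATION	calcium-channel blockers
medication	DPP-4 inhibitors	MEDICATION	DPP-4 inhibitors
medication	ezetimibe	MEDICATION	ezetimibe
medication	fibrates	MEDICATION	fibrates
medication	GLP-1 agonists	MEDICATION	GLP-1 agonists
medication	insulin	MEDICATION	insulin
medication	meglitinides	MEDICATION	meglitinides
medication	metformin	MEDICATION	metformin
medication	niacin	MEDICATION	niacin
medication	nitrates	MEDICATION	nitrates
medication	obesity	MEDICATION	obesity
medication	statins	MEDICATION	statins
medication	sulfonylureas	MEDICATION	sulfonylureas
medication	thiazide diuretics	MEDICATION	thiazide diuretics
medication	thiazolidinediones	MEDICATION	thiazolidinediones
medication	thienopyridines	MEDICATION	thienopyridines
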