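# risk factor <TAB> legal indicator attribute <TAB> time applicable (yes/no)
CAD	mention	yes
CAD	event	yes
CAD	test result	yes
CAD	symptom	yes
DIABETES	mention	yes
DIABETES	high A1c	yes
DIABETES	high glucose	yes
FAMILY_HIST	present	no
FAMILY_HIST	not present	no
HYPERLIPIDEMIA	mention	yes
HYPERLIPIDEMIA	high cholesterol	yes
HYPERLIPIDEMIA	high LDL	yes
HYPERTENSION	mention	yes
HYPERTENSION	high blood pressure	yes
MEDICATION	ACE inhibitors	yes
MEDICATION	ACE inhibitors ARBs	yes
MEDICATION	amylin	yes
MEDICATION	antidiabetes medications	yes
MEDICATION	aspirin	yes
MEDICATION	beta-blockers	yes
MEDICATION	calcium-channel blockers	yes
MEDICATION	DPP-4 inhibitors	yes
MEDICATION	ezetimibe	yes
MEDICATION	fibrates	yes
MEDICATION	GLP-1 agonists	yes
MEDICATION	insulin	yes
MEDICATION	meglitinides	yes
MEDICATION	metformin	yes
MEDICATION	niacin	yes
MEDICATION	nitrates	yes
MEDICATION	obesity	yes
MEDICATION	statins	yes
MEDICATION	sulfonylureas	yes
MEDICATION	thiazide diuretics	yes
MEDICATION	thiazolidinediones	yes
MEDICATION	thienopyridines	yes
OBESITY	mention	yes
OBESITY	BMI	yes
OBESITY	waist circumference	yes
SMOKER	current	no
SMOKER	past	no
SMOKER	never	no
SMOKER	unknown	no
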