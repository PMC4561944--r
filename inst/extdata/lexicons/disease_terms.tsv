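# disease term <TAB> risk factor
diabetes	DIABETES
diabetes mellitus	DIABETES
diabetes type 2	DIABETES
diabetes type 1	DIABETES
type 2 diabetes	DIABETES
type 1 diabetes	DIABETES
type ii diabetes	DIABETES
type i diabetes	DIABETES
diabetic	DIABETES
niddm	DIABETES
iddm	DIABETES
coronary artery disease	CAD
coronary heart disease	CAD
coronary disease	CAD
ischemic heart disease	CAD
atherosclerotic heart disease	CAD
atherosclerotic coronary disease	CAD
hypertension	HYPERTENSION
hypertensive	HYPERTENSION
high blood pressure	HYPERTENSION
elevated blood pressure	HYPERTENSION
hyperlipidemia	HYPERLIPIDEMIA
hypercholesterolemia	HYPERLIPIDEMIA
dyslipidemia	HYPERLIPIDEMIA
high cholesterol	HYPERLIPIDEMIA
elevated cholesterol	HYPERLIPIDEMIA
hyperlipidemic	HYPERLIPIDEMIA
obesity	OBESITY
obese	OBESITY
morbid obesity	OBESITY
morbidly obese	OBESITY
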