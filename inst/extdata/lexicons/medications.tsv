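# generic name <TAB> category (Table of 22 heart-disease-related categories)
lisinopril	ACE inhibitors
enalapril	ACE inhibitors
captopril	ACE inhibitors
ramipril	ACE inhibitors
benazepril	ACE inhibitors
quinapril	ACE inhibitors
fosinopril	ACE inhibitors
losartan	ACE inhibitors ARBs
valsartan	ACE inhibitors ARBs
irbesartan	ACE inhibitors ARBs
candesartan	ACE inhibitors ARBs
olmesartan	ACE inhibitors ARBs
telmisartan	ACE inhibitors ARBs
pramlintide	amylin
symlin	amylin
acarbose	antidiabetes medications
miglitol	antidiabetes medications
bromocriptine	antidiabetes medications
dapagliflozin	antidiabetes medications
canagliflozin	antidiabetes medications
empagliflozin	antidiabetes medications
aspirin	aspirin
acetylsalicylic acid	aspirin
acetyl salicylic acid	aspirin
baby aspirin	aspirin
enteric coated aspirin	aspirin
metoprolol	beta-blockers
atenolol	beta-blockers
carvedilol	beta-blockers
propranolol	beta-blockers
bisoprolol	beta-blockers
labetalol	beta-blockers
nadolol	beta-blockers
amlodipine	calcium-channel blockers
diltiazem	calcium-channel blockers
verapamil	calcium-channel blockers
nifedipine	calcium-channel blockers
felodipine	calcium-channel blockers
nicardipine	calcium-channel blockers
sitagliptin	DPP-4 inhibitors
saxagliptin	DPP-4 inhibitors
linagliptin	DPP-4 inhibitors
alogliptin	DPP-4 inhibitors
vildagliptin	DPP-4 inhibitors
ezetimibe	ezetimibe
ezetimibe-simvastatin	ezetimibe
vytorin	ezetimibe
gemfibrozil	fibrates
fenofibrate	fibrates
clofibrate	fibrates
bezafibrate	fibrates
ciprofibrate	fibrates
exenatide	GLP-1 agonists
liraglutide	GLP-1 agonists
dulaglutide	GLP-1 agonists
semaglutide	GLP-1 agonists
lixisenatide	GLP-1 agonists
insulin	insulin
insulin glargine	insulin
insulin lispro	insulin
insulin aspart	insulin
insulin detemir	insulin
nph insulin	insulin
lantus	insulin
repaglinide	meglitinides
nateglinide	meglitinides
mitiglinide	meglitinides
metformin	metformin
glucophage	metformin
metformin er	metformin
metformin xr	metformin
metformin hydrochloride	metformin
niacin	niacin
nicotinic acid	niacin
niaspan	niacin
extended-release niacin	niacin
niacin er	niacin
nitroglycerin	nitrates
trinitroglycerin	nitrates
isosorbide mononitrate	nitrates
isosorbide dinitrate	nitrates
nitropaste	nitrates
nitro patch	nitrates
orlistat	obesity
phentermine	obesity
sibutramine	obesity
lorcaserin	obesity
diethylpropion	obesity
atorvastatin	statins
simvastatin	statins
pravastatin	statins
rosuvastatin	statins
lovastatin	statins
fluvastatin	statins
pitavastatin	statins
glipizide	sulfonylureas
glyburide	sulfonylureas
glimepiride	sulfonylureas
chlorpropamide	sulfonylureas
tolbutamide	sulfonylureas
gliclazide	sulfonylureas
hydrochlorothiazide	thiazide diuretics
chlorthalidone	thiazide diuretics
indapamide	thiazide diuretics
metolazone	thiazide diuretics
chlorothiazide	thiazide diuretics
pioglitazone	thiazolidinediones
rosiglitazone	thiazolidinediones
troglitazone	thiazolidinediones
clopidogrel	thienopyridines
ticlopidine	thienopyridines
prasugrel	thienopyridines
ticagrelor	thienopyridines
cangrelor	thienopyridines
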