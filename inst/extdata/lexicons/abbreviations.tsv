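# short form <TAB> canonical long form
dm	diabetes mellitus
dm2	diabetes type 2
dmii	diabetes type 2
dm type ii	diabetes type 2
dm type 2	diabetes type 2
dm1	diabetes type 1
dmi	diabetes type 1
t2dm	diabetes type 2
t1dm	diabetes type 1
htn	hypertension
cad	coronary artery disease
chd	coronary heart disease
hld	hyperlipidemia
asa	aspirin
ntg	nitroglycerin
tng	trinitroglycerin
hctz	hydrochlorothiazide
mi	myocardial infarction
chol	cholesterol
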