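# terms marking a sentence as smoking-related (case-insensitive)
smoker
smoking
smokes
smoke
smoked
tobacco
cigarette
cigarettes
cigar
cigars
packs per year
pack years
pack-years
pack per day
ppd
nicotine
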