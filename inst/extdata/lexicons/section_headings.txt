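# known section heading phrases (case-insensitive)
medications
current medications
medications on admission
discharge medications
past medical history
medical history
history of present illness
family history
social history
allergies
assessment
plan
assessment and plan
physical exam
physical examination
laboratory data
labs
lab results
review of systems
chief complaint
impression
hospital course
problems
problem list
vital signs
record date
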