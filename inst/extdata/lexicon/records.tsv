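subject_id	medication_raw	reason_raw
S001	Fexafenedine	allergies
S002	Hydrochlorothazide	high blood pressure
S003	Metoprolol Succ ER	HTN
S004	Quinipril	high blood pressure
S005	Vit B12	fatigue
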