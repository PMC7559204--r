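canonical_name	synonyms	concept_id	atc_codes
fexofenadine	allegra	RX00001	R06A:antihistamines
hydrochlorothiazide	hctz|microzide	RX00002	C03A:diuretics
metoprolol	lopressor|toprol	RX00003	C07A:beta-adrenergic blocking agents
quinapril	accupril	RX00004	C09A:angiotensin converting enzyme inhibitors
aspirin	asa|acetylsalicylic acid|bayer aspirin	RX00005	N02B:analgesics and antipyretics|B01A:antithrombotic agents|A01A:stomatological preparations
albuterol	salbutamol|proventil|ventolin	RX00006	R03A:adrenergics, inhalants
ibuprofen	advil|motrin	RX00007	M01A:antiinflammatory and antirheumatic products, non-steroids
fluoxetine	prozac	RX00008	N06A:antidepressants
metformin	glucophage	RX00009	A10B:blood glucose lowering drugs, excluding insulins
levothyroxine	synthroid|levothroid	RX00010	H03A:thyroid preparations
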