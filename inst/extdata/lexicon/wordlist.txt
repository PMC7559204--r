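arthritis
musculoskeletal
gastritis
ulcerative
colitis
asthmatic
asthma
diarrhea
depression
mood
anxiety
diabetes
high
blood
pressure
hypertension
allergies
allergy
fatigue
pain
joint
headache
migraine
insomnia
infection
thyroid
chronic
vitamin
deficiency
reflux
acid
stomach
sleep
trouble
back
nerve
muscle
seizure
disorder
disease
heart
kidney
bladder
sinus
nausea
dizziness
swelling
cramps
spasm
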