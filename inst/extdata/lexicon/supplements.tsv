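vitamin a
vitamin b1
vitamin b6
vitamin b12
vit b12
vitamin c
vitamin d
vitamin e
multivitamin
fish oil
omega 3
calcium
magnesium
zinc
iron
folic acid
melatonin
glucosamine
chondroitin
coq10
echinacea
ginkgo biloba
st johns wort
probiotic
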