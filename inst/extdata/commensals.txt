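# Common commensal organism codes, one per line.
# Representative subset of the CDC common-commensal list; replace with the
# full institutional list for production surveillance. Matching is exact on
# the species-level code after trimming and case-folding.
staphylococcus epidermidis
staphylococcus hominis
staphylococcus haemolyticus
staphylococcus capitis
staphylococcus warneri
staphylococcus saprophyticus
staphylococcus lugdunensis
staphylococcus schleiferi
staphylococcus cohnii
staphylococcus pettenkoferi
corynebacterium striatum
corynebacterium jeikeium
corynebacterium amycolatum
corynebacterium afermentans
cutibacterium acnes
cutibacterium avidum
micrococcus luteus
micrococcus lylae
bacillus cereus
bacillus subtilis
paenibacillus polymyxa
aerococcus viridans
rothia mucilaginosa
rothia dentocariosa
dermabacter hominis
kocuria kristinae
lactobacillus rhamnosus
streptococcus mitis
streptococcus oralis
streptococcus salivarius
streptococcus sanguinis
streptococcus parasanguinis
streptococcus vestibularis
streptococcus gordonii
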