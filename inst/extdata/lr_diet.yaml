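# Lower-risk high-fat diet (high-amylose maize resistant starch), g/kg DM
available_carbohydrates: 424
protein: 119
fat: 177
total_dietary_fiber: 188
total_nsp: 73
fructans: 5
resistant_starch: 89
klason_lignin: 18
axos: 3
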