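# High-risk high-fat diet (fructose), g/kg DM
available_carbohydrates: 555
protein: 113
fat: 174
total_dietary_fiber: 100
total_nsp: 69
fructans: 6
resistant_starch: 2
klason_lignin: 18
axos: 5
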