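# 5-fluorouracil (guest) + beta-cyclodextrin (host), water, 298.15 K.
# Diffusivities in 1e-9 m^2 s^-1, K in mol^-1 dm^3.
system: 5-FU + beta-CD
d_free_drug: 1.050
d_free_carrier: 0.399
d_complex: 0.390
d_drug_infinite_dilution: 1.168
k_assoc: 10.0
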