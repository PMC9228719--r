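# Limiting diffusion coefficients of the species present in the
# 5-fluorouracil + beta-cyclodextrin system at 298.15 K (1e-9 m^2 s^-1).
# Free-species values estimated from D11 at x1 = 1 and D22 at x1 = 0; the
# complex value from the volume-additive Stokes-Einstein estimate.
species,d
5-FU,1.050
beta-CD,0.399
5-FU-beta-CD,0.390
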