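# Limiting diffusion coefficients of the species present in the
# 5-fluorouracil + sodium dodecyl sulfate system at 298.15 K
# (1e-9 m^2 s^-1). Free-species values estimated from D11 at x1 = 1 and
# D22 at x1 = 0; the complex taken equal to the micelle diffusivity.
species,d
5-FU,1.050
SDS,0.378
5-FU-SDS,0.100
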