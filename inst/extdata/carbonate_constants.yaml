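# Carbonate-system equilibrium parameterization, version 1.
#
# k0: Henry solubility of CO2 (mol kg-1 atm-1), Weiss-form polynomial in
#     absolute temperature with salinity terms:
#     ln K0 = a1 + a2*(100/T) + a3*ln(T/100)
#             + S*(b1 + b2*(T/100) + b3*(T/100)^2)
# pk1/pk2: freshwater dissociation polynomials
#     pK = a/T + b + c*T
#     plus Millero-style salinity increments
#     dpK = (A1*sqrt(S) + A2*S + A3*S^2) + (B1*sqrt(S) + B2*S)/T
#           + C1*sqrt(S)*ln(T)
# Fits are stated for roughly 0-50 degC; use above 50 degC is an
# extrapolation and is flagged in the returned metadata.
version: 1
valid_temp_c: [0, 50]
max_temp_c: 100
k0:
  a: [-60.2409, 93.4517, 23.3585]
  b: [0.023517, -0.023656, 0.0047036]
pk1:
  freshwater: {a: 3404.71, b: -14.8435, c: 0.032786}
  salinity:
    A: [13.4191, 0.0331, -5.33e-05]
    B: [-530.123, -6.103]
    C: -2.06950
pk2:
  freshwater: {a: 2902.39, b: -6.4980, c: 0.02379}
  salinity:
    A: [21.0894, 0.1248, -3.687e-04]
    B: [-772.483, -20.051]
    C: -3.3336
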