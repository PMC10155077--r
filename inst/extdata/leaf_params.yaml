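# Leaf photosynthesis parameter set (C3 soybean defaults).
# Every constant of the FvCB + Ball-Berry leaf model lives here so the
# whole leaf model is re-parameterizable from one file.

# Photosynthetic capacities at the 25 C reference temperature
vcmax25: 110.0      # umol m-2 s-1, maximum Rubisco carboxylation rate
jmax25: 195.0       # umol m-2 s-1, maximum electron transport rate
rd25: 1.2           # umol m-2 s-1, dark respiration (~ 0.011 * vcmax25,
                    #   the measured soybean leaf value; co-scales with
                    #   any Vcmax scaling factor)
tpu25: 23.0         # umol m-2 s-1, triose-phosphate utilization rate

# Light response (non-rectangular hyperbola)
theta: 0.7          # unitless curvature
leaf_absorb: 0.85   # unitless leaf absorptance
f_spectral: 0.15    # unitless spectral quality correction; light to PSII
                    #   I2 = q * leaf_absorb * (1 - f_spectral) / 2

# Rubisco kinetics at 25 C (standard C3 constants)
kc25: 404.9         # umol mol-1, Michaelis constant for CO2
ko25: 278.4         # mmol mol-1, Michaelis constant for O2
gamma_star25: 42.75 # umol mol-1, CO2 compensation point without Rd
o2: 210.0           # mmol mol-1, ambient oxygen

# Ball-Berry stomatal conductance
bb_slope: 8.0       # unitless
bb_intercept: 0.01  # mol m-2 s-1

# Arrhenius activation energies (J mol-1) for temperature scaling
ea_vcmax: 65330.0
ea_jmax: 43540.0
ea_rd: 46390.0
ea_tpu: 65330.0
ea_kc: 79430.0
ea_ko: 36380.0
ea_gamma_star: 37830.0
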