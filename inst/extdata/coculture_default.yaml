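# Default co-culture scenario: fitted weighing factors plus the
# equal-sugar, equal-inoculum reference condition. The strain blocks are
# file references resolved relative to this file.
ej2: ej2.yaml
sr8: sr8.yaml
r1: 3.75    # ethanol-feedback amendment, cellobiose strain (production)
r2: 1.76    # ethanol-feedback amendment, xylose strain (production)
r3: 1.44    # biomass accumulation weight, cellobiose strain
r4: 2.48    # biomass accumulation weight, xylose strain
r5: 1.82    # ethanol production weight, cellobiose strain
r6: 4.29    # ethanol production weight, xylose strain
S0_c: 40    # g/L cellobiose
S0_x: 40    # g/L xylose
X0_E: 0.45  # g DCW/L
X0_S: 0.45  # g DCW/L
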