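# Fitted kinetic parameters for batch xylose fermentation by the
# engineered xylose-consuming S. cerevisiae strain SR8. Substrate
# inhibition terms are omitted (no Ki/Kip keys).
name: SR8
sugar: xylose
mu_m: 0.154     # /h
Ks: 1.31        # g/L
Pm: 25.33       # g/L (fitted; curve-fit value, not the 85 g/L challenge value)
beta: 0.742
m: 0.01         # /h
Yps: 0.4        # g/g
Yxs: 0.35       # g/g
b1: 1.12        # amendment on Yps
b2: 1.32        # amendment on Yxs
vm: 0.401       # /h
Ksp: 13.32      # g/L
Pmp: 27         # g/L
gamma: 1.04
a_s0: 0
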