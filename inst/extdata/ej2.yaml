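# Fitted kinetic parameters for batch cellobiose fermentation by the
# engineered cellobiose-consuming S. cerevisiae strain EJ2.
name: EJ2
sugar: cellobiose
mu_m: 0.154     # /h
Ks: 0.568       # g/L
Ki: 204         # g/L (Haldane substrate inhibition, growth)
Pm: 69          # g/L (ethanol fully arresting growth)
beta: 1.1
m: 0.01         # /h
Yps: 0.5        # g/g
Yxs: 0.48       # g/g
b1: 1
b2: 1
vm: 0.416       # /h
Ksp: 5          # g/L
Kip: 52         # g/L (Haldane substrate inhibition, production)
Pmp: 100        # g/L (ethanol fully arresting production)
gamma: 1.1
a_s0: 0.011     # /(g/L), exp(a_s0*S0) production correction
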