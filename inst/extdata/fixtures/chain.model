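# Linear chain: uptake (U=10) feeding the biomass reaction.
# Partial-inhibition showcase: with one drug on the uptake and tau = 0.5,
# half-dose (h = 0.5) halves the chain at side effect 10; the ON/OFF model
# (P = 0) must stop it completely at side effect 20.
model: chain
biomass: R_BIO
metabolite: A
reaction: R_UP rev=0 lb=0 ub=10 A:1
reaction: R_BIO rev=0 lb=0 ub=10 A:-1
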