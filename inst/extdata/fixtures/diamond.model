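# Rerouting demo: a two-step upstream chain feeds A; A reaches the biomass
# precursor B either directly (R_A) or through a two-step bypass
# (R_M1, R_M2 via C). Blocking R_A reroutes flux through the bypass
# (side effect 30) instead of shutting the chain down (side effect 40).
model: diamond
biomass: R_BIO
metabolite: A0 A B C
reaction: R_UP rev=0 lb=0 ub=10 A0:1
reaction: R_C rev=0 lb=0 ub=10 A0:-1 A:1
reaction: R_A rev=0 lb=0 ub=10 A:-1 B:1
reaction: R_M1 rev=0 lb=0 ub=10 A:-1 C:1
reaction: R_M2 rev=0 lb=0 ub=10 C:-1 B:1
reaction: R_BIO rev=0 lb=0 ub=10 B:-1
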