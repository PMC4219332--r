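# Up-regulation demo: biomass precursor B is reachable from A directly
# (R_A, capacity 6) or through C (R_M1 then R_M2). Untreated, the direct
# route is saturated and the bypass carries 4. Inhibiting R_A pushes flux
# onto the bypass: with tau = 1.5 on R_M2 the optimum is h = 0.5
# (bypass flux 7 >= 6) at side effect 9.
model: activation
biomass: R_BIO
metabolite: A B C
reaction: R_UP rev=0 lb=0 ub=10 A:1
reaction: R_A rev=0 lb=0 ub=6 A:-1 B:1
reaction: R_M1 rev=0 lb=0 ub=10 A:-1 C:1
reaction: R_M2 rev=0 lb=0 ub=10 C:-1 B:1
reaction: R_BIO rev=0 lb=0 ub=20 B:-1
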