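# Two parallel uptakes feed the biomass precursor. Drug DK targets only
# R_IN1 (a subset of DL's targets); capping the biomass flux requires both
# uptakes inhibited, so DL alone is optimal and DK is superfluous: the
# anti-overselection term drives h_DK to 0.
model: superfluous
biomass: R_BIO
metabolite: A
reaction: R_IN1 rev=0 lb=0 ub=10 A:1
reaction: R_IN2 rev=0 lb=0 ub=10 A:1
reaction: R_BIO rev=0 lb=0 ub=20 A:-1
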