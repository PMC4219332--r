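fluxmod structured model format, version 1
==========================================

Line-oriented plain text. '#' starts a comment (to end of line); blank
lines are ignored. Records:

  model: <name>                    optional, default "model"
  biomass: <reaction-id>           the growth/objective reaction
  metabolite: <id> [<id> ...]      declares metabolites (repeatable)
  reaction: <id> rev=<0|1> lb=<num> ub=<num> [<met>:<coef> ...]

Ids must not contain whitespace or ':'. Every metabolite referenced by a
reaction must be declared. Coefficients are signed (negative = consumed,
positive = produced). rev=1 marks a reversible reaction; on conversion to
the canonical irreversible form a reversible reaction with lb < 0 is split
into <id>_f (bounds [0, ub]) and <id>_b (bounds [0, -lb], negated column).

Drug catalog format, version 1
------------------------------

  drug: <id> targets=<rid1>,<rid2>,... [levels=<l1>,<l2>,...]

targets are reaction ids of the original network (a drug targeting a
reversible reaction constrains both halves of the split). levels, if
present, are strictly increasing dose-response inhibition levels in (0,1)
used by the "dose" encoding scheme.
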