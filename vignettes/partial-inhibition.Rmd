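---
title: "Partial inhibition in bilevel flux balance analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial inhibition in bilevel flux balance analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmod)
```

## The model

A metabolic network at steady state is a polytope
$W = \{v \in \mathbb{R}^r : Sv = 0,\; 0 \le v_i \le U_i\}$, where $S$ is the
$m \times r$ stoichiometric matrix. Reversible reactions are first
decomposed into forward/backward irreversible pairs
(`make_irreversible()`), so all fluxes are non-negative; a drug targeting
a reversible enzyme constrains both halves. The untreated state $v^{ut}$
is the flux vector maximizing the biomass flux; because FBA optima can be
degenerate, `fba_reference()` determinizes with a lexicographic second
stage (fix the optimum, minimize total flux $\sum_i v_i$) and records the
rule in `tie_break_tag`.

A treatment is a dosage vector $h \in [0,1]^d$. Drug $k$ at dosage $h_k$
tightens the bound of each of its targets $i \in T_k$ to
$v_i \le U_i(1 - h_k)$; with one constraint per (drug, target) pair the
effective bound is automatically $U_i(1 - \max_k h_k)$ — the maximum
inhibition over the drugs hitting the enzyme, with no allosteric
interaction. The cellular response is L1-MOMA,
$v^{tr}(h) = \arg\min_{v \in W(h)} \lVert v - v^{ut}\rVert_1$, and the
*side effect* of the treatment is $\lVert v^{tr}(h) - v^{ut}\rVert_1$.
The design problem is the bilevel program: over $h$, minimize the side
effect subject to $v^{tr}_{mod}(h) \le \tau\, v^{ut}_{mod}$ (inhibition,
$0 \le \tau < 1$) or $\ge \tau\, v^{ut}_{mod}$ (activation, $\tau > 1$).

## Single-level reformulation

With $h$ fixed, the inner problem is an LP in $(v, a)$ (deviations
$a_i \ge \pm(v_i - v^{ut}_i)$):

$$\min \textstyle\sum_i a_i \quad \text{s.t.} \quad Sv = 0,\; v_i \le U_i,\;
v_i \le U_i(1 - h_k),\; v_i - a_i \le v^{ut}_i,\; -v_i - a_i \le -v^{ut}_i,
\; v, a \ge 0.$$

Deriving its Lagrangian dual (multipliers $\mu$ free, $\lambda, \delta,
\alpha, \beta \ge 0$ for the four inequality families) gives the dual
constraints

$$\sum_i S_{ij}\mu_i + \lambda_j + \sum_{p:\,i(p)=j} \delta_p + \alpha_j -
\beta_j \ge 0, \qquad \alpha_j + \beta_j \le 1,$$

and the strong-duality equality used as a constraint row:

$$\sum_i a_i + \sum_j U_j \lambda_j + \sum_p U_{i(p)}\,\delta_p\,(1 -
h_{k(p)}) + \sum_j (\alpha_j - \beta_j)\, v^{ut}_j = 0 .$$

Since the equality can hold only at a primal/dual optimal pair, any
feasible point of the combined system has $v$ inner-optimal — the bilevel
nesting collapses into one program, with the threshold on $v_{mod}$ and
the dosage variables added on top. The derivation is re-verified
numerically on every test run: fixed-$h$ primal and dual LPs agree to
1e-9, and every reported optimum carries a duality residual $\le$ 1e-6.

The products $\delta_p h_k$ make the row bilinear. Writing
$h_k = \sum_n w_n x_{k,n}$ over Booleans restores linearity via one
product variable $z_{p,n} = \delta_p x_{k,n}$ per pair, each exactly
linearized by $0 \le z \le \delta^{max} x$, $z \le \delta$,
$\delta - \delta^{max}(1 - x) \le z$ — valid because $\delta_p$ is bounded
by $\delta^{max}_p$ (see *Numerical choices*).

## Dosage encodings

**Binary expansion** (default): weights $(1/2^P, 1/2, \dots, 1/2^P)$ on
$P+1$ Booleans $x_{k,0..P}$ give every value of the grid $\{m/2^P\}$ —
$2^P + 1$ dosages from $P+1$ bits, the most precision per Boolean. $P = 0$
is the ON/OFF model. Because $x_{k,0}$ duplicates the smallest weight,
$h_k = 1$ is reachable but encodings would be redundant; the constraint
$P\,x_{k,0} \le \sum_{j \ge 1} x_{k,j}$ allows $x_{k,0} = 1$ only when all
other bits are set. At $P = 0$ the constraint is omitted (only $x_{k,0}$
exists; the division by $P$ in its normalized form is undefined).

**Dose-response levels**: when a drug has measured inhibition levels
$0 < \ell_1 < \dots < \ell_Q < 1$, the weights are the increments
$(\ell_1, \ell_2 - \ell_1, \dots, 1 - \ell_Q)$ and valid dosage vectors
are prefix-of-ones chains ($x_{k,j+1} \le x_{k,j}$), so the achievable set
is exactly $\{0, \ell_1, \dots, \ell_Q, 1\}$. We deliberately orient the
chain this way: the opposite ordering, combined with increment
coefficients, could never produce the lowest level alone, contradicting
the purpose of matching the measured levels. A telescoping check (all
bits on $\to h = 1$) is part of the test suite.

**Anti-overselection**: among side-effect-equivalent optima (e.g. a drug
whose target set is contained in another's), the objective
$\sum_i a_i + b \sum_k h_k$ with $b = 10^{-3}$ (three orders of magnitude
below the default flux-bound scale) discards superfluous drugs without
ever reordering solutions whose side effects genuinely differ.

## Numerical choices

* **Solver.** All LPs and MILPs go to HiGHS through scipy, batched (many
  problems per subprocess call). MILP relative gap 0 on the instance
  sizes used here; integrality tolerance 1e-6; feasibility tolerance 1e-9
  reported in solution metadata.
* **$\delta^{max}$ (big-M).** Default uniform
  $\max(1, \kappa \cdot \max_i U_i)$, $\kappa = 10$;
  `estimate_delta_max(method = "sampled")` instead solves the explicit
  dual LP at extreme dosages and takes 10× the observed maxima. A bound
  that is too small does not silently corrupt the optimum: the
  strong-duality row becomes unsatisfiable and the MILP reports
  infeasibility. As a belt-and-braces check, every MILP solution is
  re-validated by an independent `moma_l1()` solve at the decoded $h$
  (relative agreement 1e-6) with automatic 10× enlargement and re-solve on
  mismatch; a $\delta$ within 1% of its bound is flagged
  (`delta_bound_ok`).
* **L1 degeneracy.** The L1 ball is not strictly convex, so $v^{tr}$ can
  be non-unique while the side effect is unique; contracts and tests
  assert on values, not coordinates, except where uniqueness is provable.
  Two determinizations address the places where $v_{mod}$ itself matters:
  (i) *feasibility* of a dosage (oracle and MILP alike) is optimistic —
  a dosage qualifies iff the inner-optimal face contains a point meeting
  the threshold, which is exactly what the MILP's shared $(v, a)$
  variables express, and what a second LP (extremize $v_{mod}$ at fixed
  optimal side effect) implements in the oracle; (ii) the *nonlinearity
  index* of a screening record evaluates singles and combined at the
  mode-consistent extreme of the optimal face (max $v_{mod}$ for
  activation, min for inhibition), which makes $\eta$ well defined and
  exactly 0 for single-drug treatments. Raw interaction surfaces keep the
  solver's vertex; their known irregularity is why the smooth L2 variant
  is provided as a cross-check.
* **L2-MOMA.** Solved as a bound- and equality-constrained least-squares
  problem with scipy's `trust-constr` (accuracy ~1e-4). It is a
  cross-check of surface shape, not part of the MILP pipeline.
* **Reversible reactions with non-negative lower bounds** are treated as
  irreversible with a warning; positive lower bounds are relaxed to 0 in
  the canonical form (the bilevel machinery assumes $L_i = 0$) and
  enforced only in the reference-FBA stage, where they belong
  biologically (nutrient availability of the untreated organism).
* **Ties among MILP optima** are accepted as returned by the solver
  (deterministic for fixed input); the exhaustive oracle breaks ties
  lexicographically in $h$ for reproducibility.

## The synthetic generator: what it emulates and what it does not

`generate_synthetic()` emulates small random test instances: an uptake →
internal chain → biomass backbone (guaranteeing a connected network with
strictly positive biomass optimum), plus random internal conversions, a
fraction of them reversible (default 0.2), with bounds drawn from 5–20
flux units and uptake capacity 10, and drugs drawing uniform target sets
over the non-biomass reactions. Instances are fully determined by the
seed. These networks have realistic *local* structure (branching,
rerouting, reversibility, capacity bottlenecks) but none of the global
organization of genome-scale reconstructions: no compartments, cofactor
coupling, gene–protein–reaction rules or biomass composition. A green
oracle-equivalence test therefore establishes the correctness of the
reformulation machinery on the stated instance distribution — not
biological predictivity of any particular screen.

## Screening and deduplication

`screen_reactions()` treats every reaction as the modulation objective
across a threshold list ($\tau < 1$ inhibit, $\tau > 1$ activate);
zero-flux reactions are skipped with a marker (a fractional threshold on
zero flux is vacuous). When the identical dosage vector solves several
thresholds for one reaction, it is kept only at the most stringent one
(smallest inhibition $\tau$ / largest activation $\tau$); duplicate
detection uses exact equality of the decoded $h$ vectors. Summaries are
the four standard tables: solution counts per threshold, cardinality
frequencies, side-effect values and $\eta$ values (the latter two pooled
over thresholds).

## Known limitations

* The optimization back end is an external python process; extremely
  large models pay JSON serialization costs (the batched protocol
  amortizes interpreter startup, not matrix encoding).
* Genome-scale SBML models are supported as inputs but not bundled or
  exercised by tests; the fbc reader covers bounds, objectives and
  boundary species, not gene associations or compartment semantics.
* L2-MOMA accuracy (~1e-4) is below LP accuracy by design of the
  `trust-constr` stopping rules; do not use it where 1e-9 agreement
  matters.
* No loopless/thermodynamic constraints; a rerouting solution may use a
  thermodynamically unrealistic cycle if the input model admits one.
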