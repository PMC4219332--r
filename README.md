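# fluxmod

Minimal-side-effect drug combinations on metabolic networks, with
**partial** enzyme inhibition, via a single-level MILP reformulation of a
bilevel flux-balance problem.

## The problem

Given a stoichiometric metabolic model (matrix **S**, flux bounds
0 ≤ vᵢ ≤ Uᵢ after decomposing reversible reactions) and a set of *d* drugs,
each inhibiting a set of target reactions T_k, find the dosage vector
**h** ∈ [0,1]^d that

* modulates an objective reaction past a threshold
  (v_mod ≤ τ·v_modᵘᵗ to inhibit, v_mod ≥ τ·v_modᵘᵗ with τ > 1 to
  activate), and
* minimally perturbs the rest of the network, where the cell's response
  to treatment is predicted by L1-MOMA:
  vᵗʳ(**h**) = argmin ‖v − vᵘᵗ‖₁ over the inhibited flux polytope
  W(**h**) = {Sv = 0, vᵢ ≤ Uᵢ(1 − h_k) for every drug k targeting i},
  and the *side effect* is ‖vᵗʳ(**h**) − vᵘᵗ‖₁.

This is a bilevel (min-min) program. fluxmod folds the inner MOMA problem
into a single mixed-integer linear program by LP strong duality: the inner
problem's constraints, its explicitly derived dual constraints, and one
equality row forcing primal objective = dual objective. Each dosage h_k is
a convex combination of P+1 Boolean variables (binary expansion on the
grid {m/2^P}, or the measured dose-response levels), and the bilinear
dual-times-Boolean products are linearized exactly with big-M rows. P = 0
recovers the classical ON/OFF knockout model; P ≥ 1 is what makes
*partial* inhibition expressible while keeping the problem linear.

On top of the core solver the package provides: an exhaustive-search
oracle over the dosage grid, drug-interaction surfaces (L1 and the smooth
L2 cross-check), a nonlinearity/synergy index
η = (Σ_k v_modᵗʳ(h_k e_k) − (d−1)·v_modᵘᵗ − v_modᵗʳ(**h**)) /
(v_modᵘᵗ − v_modᵗʳ(**h**)) (0 = additive, >0 = synergistic),
an all-reactions screening protocol with most-stringent-threshold
deduplication, model I/O (structured text, TSV triplets, SBML-fbc), a
synthetic instance generator, and CLI drivers.

## Requirements and installation

R (≥ 4.1) with jsonlite and xml2, plus a `python` (≥ 3.8) on the PATH
with numpy and scipy ≥ 1.9 — all LPs/MILPs are solved by scipy's HiGHS
interface through a batched subprocess bridge; no R solver library is
needed.

```sh
R CMD INSTALL .
R -e 'testthat::test_dir("tests/testthat", package = "fluxmod", load_package = "installed")'
```

## Worked example

The bundled `"chain"` fixture is a two-reaction chain (uptake, U = 10,
feeding the biomass reaction) with one drug on the uptake. Ask for the
biomass flux to be at most half its untreated value (τ = 0.5):

```r
library(fluxmod)
fx  <- fixture("chain")
net <- make_irreversible(fx$network)
ref <- fba_reference(net)
ref$v_ut
#>  R_UP R_BIO
#>    10    10

solve_bilevel(net, ref, fx$catalog, mod_id = "R_BIO", tau = 0.5, P = 1)
#> <treatment_solution (bilevel-milp, inhibit): mod=R_BIO tau=0.5 P=1>
#>   h: D1=0.5
#>   side effect: 10;  v_mod: 5;  status: optimal

solve_bilevel(net, ref, fx$catalog, mod_id = "R_BIO", tau = 0.5, P = 0)
#> <treatment_solution (bilevel-milp, inhibit): mod=R_BIO tau=0.5 P=0>
#>   h: D1=1
#>   side effect: 20;  v_mod: 0;  status: optimal
```

At precision P = 1 the half dose h = 0.5 trims the chain to (5, 5) — side
effect 10, exactly the requested modulation. The ON/OFF model (P = 0) can
only stop the chain completely: side effect 20, twice the perturbation.
That gap is the point of partial inhibition. The exhaustive oracle
(`exhaustive_oracle()`, here 3 MOMA LPs) certifies the same optimum:

```r
exhaustive_oracle(net, ref, fx$catalog, "R_BIO", 0.5, P = 1)
#> <treatment_solution (exhaustive, inhibit): mod=R_BIO tau=0.5 P=1>
#>   h: D1=0.5
#>   side effect: 10;  v_mod: 5;  status: optimal
```

Every MILP solution carries a strong-duality residual (≤ 1e-6) and is
re-validated by an independent MOMA solve at the returned dosage.

## Command line

```sh
Rscript inst/cli/fluxmod optimize --config run.json   # single optimization
Rscript inst/cli/fluxmod screen   --config run.json   # all-reactions screen
Rscript inst/cli/fluxmod surface  --config run.json   # drug-pair surface
Rscript inst/cli/fluxmod generate --config gen.json   # synthetic fixtures
Rscript inst/cli/fluxmod oracle   --config run.json   # exhaustive check
```

Configs are JSON (`model`, `catalog`, `mod_id`, `tau`, `mode`, `P`, ...);
reports embed a config hash, seed, solver identity and tolerances for
replay. File formats are documented in
`inst/extdata/structured-model-schema.txt`.

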