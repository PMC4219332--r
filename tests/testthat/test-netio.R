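# Model I/O, canonicalization and the reference flux state.

test_that("structured/tsv round trips preserve the model; bad input errors", {
  net <- make_branched()
  for (fmt in c("structured", "tsv")) {
    path <- withr::local_tempfile(fileext = if (fmt == "tsv") ".tsv" else ".txt")
    write_network(net, path, format = fmt)
    back <- load_network(path, format = fmt)
    expect_equal(back$stoich, net$stoich)
    expect_equal(back$lower_bounds, net$lower_bounds)
    expect_equal(back$upper_bounds, net$upper_bounds)
    expect_equal(back$reversible, net$reversible)
    expect_equal(back$biomass_id, net$biomass_id)
  }
  # reversibility flags echo the input
  expect_equal(unname(net$reversible), c(F, F, F, F, T, F))
  # duplicate reaction id is reported by name
  path <- withr::local_tempfile()
  writeLines(c("biomass: R1", "metabolite: A",
               "reaction: R1 rev=0 lb=0 ub=1 A:1",
               "reaction: R1 rev=0 lb=0 ub=1 A:-1"), path)
  expect_error(load_network(path), "duplicate reaction id: R1")
  # missing biomass is an explicit error that biomass_id= overrides
  writeLines(c("metabolite: A", "reaction: R1 rev=0 lb=0 ub=1 A:1",
               "reaction: R2 rev=0 lb=0 ub=1 A:-1"), path)
  expect_error(load_network(path), "biomass")
  expect_equal(load_network(path, biomass_id = "R2")$biomass_id, "R2")
})

test_that("random synthetic networks round-trip through both writers", {
  gen <- generate_synthetic(4, 7, 2, 2, seed = 11, check = FALSE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(gen$network, path)
  back <- load_network(path)
  expect_equal(back$stoich, gen$network$stoich)
  expect_equal(back$upper_bounds, gen$network$upper_bounds)
  cpath <- withr::local_tempfile()
  write_drug_catalog(gen$catalog, cpath)
  expect_equal(read_drug_catalog(cpath)$target_sets, gen$catalog$target_sets)
})

test_that("a minimal SBML model is parsed with fbc bounds and objective", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy">',
    '<listOfParameters>',
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="ub10" value="10" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '<species id="Aext" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_UP" reversible="false" lowerFluxBound="lb0" upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="Aext" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_BIO" reversible="false" lowerFluxBound="lb0" upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<listOfObjectives><listOfFluxObjectives>',
    '<fluxObjective reaction="R_BIO" coefficient="1"/>',
    '</listOfFluxObjectives></listOfObjectives>',
    '</model></sbml>'), path)
  net <- load_network(path, format = "sbml")
  expect_equal(net$reaction_ids, c("R_UP", "R_BIO"))
  expect_equal(net$metabolite_ids, "A")  # boundary species dropped
  expect_equal(unname(net$upper_bounds), c(10, 10))
  expect_equal(net$biomass_id, "R_BIO")
  expect_equal(unname(net$stoich["A", ]), c(1, -1))
})

test_that("make_irreversible splits reversible reactions correctly", {
  net <- make_branched()
  can <- make_irreversible(net)
  expect_true(can$canonical)
  expect_equal(length(can$reaction_ids), 7)  # one split pair
  expect_equal(names(can$split_map), "R_SH")
  pair <- can$split_map[["R_SH"]]
  expect_equal(unname(can$upper_bounds[pair["forward"]]), 4)
  expect_equal(unname(can$upper_bounds[pair["backward"]]), 4)
  expect_equal(unname(can$stoich[, pair["backward"]]),
               -unname(can$stoich[, pair["forward"]]))
  expect_true(all(can$lower_bounds == 0))
  # already-irreversible network passes through unchanged
  chain <- make_chain()
  expect_identical(make_irreversible(chain), chain)
  # reversible flag with non-negative lower bound: warning, no split
  odd <- metabolic_network(matrix(c(1, -1), 1, 2), c(0, 2), c(5, 5),
                           c(FALSE, TRUE), c("R1", "R2"), "A", "R2")
  expect_warning(canodd <- make_irreversible(odd), "treated as irreversible")
  expect_equal(length(canodd$reaction_ids), 2)
  expect_equal(unname(canodd$lower_bounds), c(0, 0))
  expect_equal(unname(canodd$ref_lower), c(0, 2))
})

test_that("feasible signed fluxes map to feasible non-negative split fluxes", {
  net <- make_branched()
  can <- make_irreversible(net)
  # feasible points: random convex combinations of the polytope's vertices
  V <- enumerate_vertices(net$stoich, net$lower_bounds, net$upper_bounds)
  expect_gt(nrow(V), 0)
  set.seed(42)
  P <- t(vapply(1:20, function(i) {
    w <- stats::runif(nrow(V)); w <- w / sum(w)
    colSums(V * w)
  }, numeric(ncol(V))))
  for (i in seq_len(nrow(P))) {
    v <- stats::setNames(P[i, ], net$reaction_ids)
    vs <- fluxmod:::split_fluxes(can, net, v)
    expect_true(all(vs >= -1e-9))
    expect_lt(max(abs(can$stoich %*% vs)), 1e-9)
    expect_true(all(vs <= can$upper_bounds + 1e-9))
  }
})

test_that("reference FBA handles chains, dead networks and degenerate optima", {
  ch <- canonical_ref(make_chain())
  expect_equal(unname(ch$ref$v_ut), c(10, 10), tolerance = 1e-7)
  expect_equal(ch$ref$objective_value, 10, tolerance = 1e-9)
  expect_equal(ch$ref$tie_break_tag, "max-objective+lexmin-total-flux")
  # zero uptake capacity: all-zero fluxes, objective 0
  dead <- metabolic_network(matrix(c(1, -1), 1, 2), 0, c(0, 10),
                            FALSE, c("R_UP", "R_BIO"), "A", "R_BIO")
  refd <- fba_reference(dead)
  expect_equal(unname(refd$v_ut), c(0, 0))
  expect_equal(refd$objective_value, 0)
  # non-canonical input refused
  expect_error(fba_reference(make_branched()), "canonical")
})

test_that("FBA optimum matches an independent vertex-enumeration oracle", {
  cb <- canonical_ref(make_branched())
  expect_equal(cb$ref$objective_value,
               vertex_fba_value(cb$net, "R_BIO"), tolerance = 1e-9)
  # canonicalization preserves the optimum computed on the signed network
  net <- make_branched()
  signed_value <- max(enumerate_vertices(net$stoich, net$lower_bounds,
                                         net$upper_bounds)[,
                      match("R_BIO", net$reaction_ids)])
  expect_equal(cb$ref$objective_value, signed_value, tolerance = 1e-9)
  # v_ut satisfies steady state and bounds
  expect_lt(max(abs(cb$net$stoich %*% cb$ref$v_ut)), 1e-9)
  expect_true(all(cb$ref$v_ut >= -1e-9 &
                    cb$ref$v_ut <= cb$net$upper_bounds + 1e-9))
})

test_that("generator is seed-deterministic and always yields balanced, feasible nets", {
  g1 <- generate_synthetic(5, 8, 2, 2, seed = 1, check = FALSE)
  g2 <- generate_synthetic(5, 8, 2, 2, seed = 1, check = FALSE)
  expect_identical(g1, g2)
  ref <- fba_reference(make_irreversible(g1$network))
  expect_gt(ref$objective_value, 0)
  expect_error(generate_synthetic(5, 3, 1, 1, seed = 1), "n_reactions")
  # 100 seeds: every generated network is steady-state balanced at v_ut
  nets <- lapply(1:100, function(s)
    make_irreversible(generate_synthetic(4, 7, 2, 2, seed = s,
                                         check = FALSE)$network))
  stage1 <- lapply(nets, function(n)
    fluxmod:::fba_reference_problems(n, match("BIO", n$reaction_ids))$stage1)
  res1 <- fluxmod:::solve_programs(stage1)
  expect_true(all(vapply(res1, `[[`, "", "status") == "optimal"))
  stage2 <- lapply(seq_along(nets), function(i)
    fluxmod:::fba_stage2_problem(nets[[i]],
                                 match("BIO", nets[[i]]$reaction_ids),
                                 -res1[[i]]$objective, 1e-9))
  res2 <- fluxmod:::solve_programs(stage2)
  ok <- vapply(seq_along(nets), function(i) {
    v <- res2[[i]]$x
    res2[[i]]$status == "optimal" &&
      max(abs(nets[[i]]$stoich %*% v)) < 1e-9
  }, TRUE)
  expect_equal(sum(ok), 100)
  # and the biomass optimum is strictly positive in every instance
  expect_true(all(vapply(res1, function(r) -r$objective, 0) > 0))
})
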