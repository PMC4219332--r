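# Exhaustive oracle bookkeeping, nonlinearity index, interaction surfaces
# and the screening protocol with most-stringent-threshold deduplication.

test_that("oracle enumerates (2^P+1)^d grid points and respects the cap", {
  fx <- fixture("superfluous-drug")
  cc <- canonical_ref(fx$network)
  ora <- exhaustive_oracle(cc$net, cc$ref, fx$catalog, "R_BIO", 0.25, P = 1)
  expect_equal(ora$n_evaluations, 9)  # (2^1+1)^2
  expect_error(exhaustive_oracle(cc$net, cc$ref, fx$catalog, "R_BIO", 0.25,
                                 P = 2, cap = 10), "cap")
  # tau = 0 on the chain: only the full stop of the single uptake works
  cc2 <- canonical_ref(make_chain())
  ora0 <- exhaustive_oracle(cc2$net, cc2$ref, chain_catalog(), "R_BIO", 0,
                            P = 2)
  expect_equal(unname(ora0$h), 1)
})

test_that("nonlinearity index follows its defining formula", {
  # single active drug: telescoping gives exactly 0
  expect_equal(nonlinearity_index(10, c(7), 7), 0)
  expect_equal(nonlinearity_index(10, c(7, 10), 7), 0)
  # direct arithmetic: (8 + 7 - 10 - 2) / (10 - 2) = 3/8
  expect_equal(nonlinearity_index(10, c(8, 7), 2), 0.375)
  # exact superposition: combined = sum(singles) - (d-1) v_ut -> 0
  singles <- c(8, 6, 9)
  comb <- sum(singles) - 2 * 10
  expect_equal(nonlinearity_index(10, singles, comb), 0)
  # unchanged objective flux: undefined, not a number
  expect_true(is.na(nonlinearity_index(10, c(10, 10), 10)))
  expect_error(nonlinearity_index(10, numeric(0), 5), "at least one")
})

test_that("interaction surface has the right grid, corner and masking", {
  fx <- fixture("superfluous-drug")
  cc <- canonical_ref(fx$network)
  surf <- interaction_surface(cc$net, cc$ref, fx$catalog, "R_BIO",
                              "DK", "DL", P = 2)
  expect_equal(dim(surf$flux_pct), c(5, 5))  # 2^2+1 per axis
  expect_equal(surf$grid_a, (0:4) / 4)
  # untreated corner: 100% flux, eta undefined
  expect_equal(surf$flux_pct[1, 1], 100, tolerance = 1e-6)
  expect_true(is.na(surf$eta[1, 1]))
  # DK's only target is shared with DL: the flux depends on max(h_a, h_b)
  # only through the shared bound plus DL's second target
  for (ia in 1:5) for (ib in 1:5) {
    expect_equal(surf$flux_pct[ia, ib],
                 100 * (min(1 - surf$grid_a[ia], 1 - surf$grid_b[ib]) * 10 +
                          (1 - surf$grid_b[ib]) * 10) / 20,
                 tolerance = 1e-5)
  }
  # eta on the surface equals nonlinearity_index recomputed cell-wise
  jmod <- match("R_BIO", cc$net$reaction_ids)
  for (cell in list(c(2, 2), c(3, 5), c(5, 3))) {
    h <- c(surf$grid_a[cell[1]], surf$grid_b[cell[2]])
    eta_direct <- fluxmod:::eta_for_h(cc$net, cc$ref, fx$catalog, jmod, h)
    expect_equal(surf$eta[cell[1], cell[2]], eta_direct, tolerance = 1e-6)
  }
  expect_error(interaction_surface(cc$net, cc$ref, fx$catalog, "R_BIO",
                                   "DK", "DK", P = 1), "must differ")
  expect_error(interaction_surface(cc$net, cc$ref, fx$catalog, "R_BIO",
                                   "DK", "NOPE", P = 1), "unknown drug")
})

test_that("a two-target chain surface depends only on the max dosage", {
  # both drugs target the same single uptake: per-pair bound dominance
  cc <- canonical_ref(make_chain())
  catalog <- drug_catalog(c("DA", "DB"), list("R_UP", "R_UP"))
  surf <- interaction_surface(cc$net, cc$ref, catalog, "R_BIO", "DA", "DB",
                              P = 2)
  for (ia in 1:5) for (ib in 1:5)
    expect_equal(surf$flux_pct[ia, ib],
                 100 * (1 - max(surf$grid_a[ia], surf$grid_b[ib])),
                 tolerance = 1e-5)
})

test_that("screening skips zero-flux reactions and dedups per threshold", {
  fx <- fixture("diamond")  # v_ut has two zero-flux bypass reactions
  cc <- canonical_ref(fx$network)
  scr <- screen_reactions(cc$net, cc$ref, fx$catalog, tau_list = c(0.1, 0.5),
                          P = 0, mod_ids = c("R_M1", "R_A", "R_BIO"),
                          compute_eta = FALSE)
  rec <- scr$records
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$status[rec$mod_id == "R_M1"] == "skipped-zero-flux"))
  # R_BIO cannot be inhibited by the rerouting drug at all
  expect_true(all(rec$status[rec$mod_id == "R_BIO"] == "infeasible"))
  # R_A at P=0: the only solution h=1 appears at both taus -> kept at 0.1
  ra <- rec[rec$mod_id == "R_A" & rec$status == "optimal", ]
  expect_equal(nrow(ra), 2)
  expect_true(ra$kept[ra$tau == 0.1])
  expect_false(ra$kept[ra$tau == 0.5])
})

test_that("activation screening keeps duplicates at the largest tau", {
  fx <- fixture("activation")
  cc <- canonical_ref(fx$network)
  # P=0: h=1 is the only qualifying dose at both activation thresholds
  scr <- screen_reactions(cc$net, cc$ref, fx$catalog,
                          tau_list = c(1.5, 2.0), P = 0,
                          mod_ids = "R_M2", compute_eta = FALSE)
  rec <- scr$records
  expect_equal(rec$status, rep("optimal", 2))
  expect_false(rec$kept[rec$tau == 1.5])
  expect_true(rec$kept[rec$tau == 2.0])
  # single-drug solutions have eta = 0 when computed
  scr2 <- screen_reactions(cc$net, cc$ref, fx$catalog, tau_list = 1.5,
                           P = 2, mod_ids = "R_M2")
  expect_equal(scr2$records$eta, 0, tolerance = 1e-6)
  s <- summary(scr2)
  expect_equal(s$n_solutions$kept, 1)
  expect_equal(unname(s$cardinality["1"]), 1L)
})

test_that("tau list validation and feasibility nesting in P", {
  fx <- fixture("chain")
  cc <- canonical_ref(fx$network)
  expect_error(screen_reactions(cc$net, cc$ref, fx$catalog, numeric(0)),
               "non-empty")
  expect_error(screen_reactions(cc$net, cc$ref, fx$catalog, c(0.5, 1)),
               "tau values")
  # grid refinement nests: everything feasible at P stays feasible at P+1
  for (tau in c(0.3, 0.7)) {
    n_ok <- vapply(0:2, function(P) {
      scr <- screen_reactions(cc$net, cc$ref, fx$catalog, tau, P = P,
                              compute_eta = FALSE)
      sum(scr$records$status == "optimal")
    }, 0L)
    expect_true(all(diff(n_ok) >= 0))
  }
})
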