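# The single-level MILP: block structure, strong duality, and agreement
# with exhaustive enumeration on hand-checkable instances.

count_instance <- function() {
  fx <- fixture("superfluous-drug")
  cc <- canonical_ref(fx$network)
  list(net = cc$net, ref = cc$ref, catalog = fx$catalog)
}

test_that("primal block emits m + r + t + 2r rows and P+1 Booleans per drug", {
  ci <- count_instance()
  r <- length(ci$net$reaction_ids); m <- length(ci$net$metabolite_ids)
  t_pairs <- nrow(fluxmod:::target_pairs(ci$catalog, ci$net))
  expect_equal(t_pairs, 3)  # DK: 1 target, DL: 2
  for (P in c(0L, 2L)) {
    enc <- fluxmod:::drug_encodings(ci$catalog, P)
    model <- fluxmod:::new_mip()
    blk <- build_primal_block(model, ci$net, ci$ref, ci$catalog, enc)
    expect_equal(sum(blk$n_rows), m + r + t_pairs + 2 * r)
    expect_equal(fluxmod:::n_rows(model), m + r + t_pairs + 2 * r)
    expect_equal(lengths(blk$x), rep(P + 1L, 2), ignore_attr = TRUE)
  }
  # 8 drugs at P = 5: 48 Boolean dosage variables in the whole problem
  gen <- generate_synthetic(5, 12, 8, 2, seed = 3, check = FALSE)
  net <- make_irreversible(gen$network)
  enc <- fluxmod:::drug_encodings(gen$catalog, 5)
  model <- fluxmod:::new_mip()
  blk <- build_primal_block(model, net, rep(0, length(net$reaction_ids)),
                            gen$catalog, enc)
  expect_equal(sum(lengths(blk$x)), 48)
})

test_that("dual block emits 2r rows; untargeted reactions carry no delta", {
  ci <- count_instance()
  r <- length(ci$net$reaction_ids)
  model <- fluxmod:::new_mip()
  blk <- build_dual_block(model, ci$net, ci$ref, ci$catalog, delta_max = 100)
  expect_equal(fluxmod:::n_rows(model), 2 * r)
  # R_BIO is not targeted: its (7g) row references no delta variable
  jbio <- match("R_BIO", ci$net$reaction_ids)
  row <- model$row_i[[jbio]]
  expect_false(any(blk$delta %in% row))
  # R_IN1 is targeted by both drugs: two delta terms
  jin1 <- match("R_IN1", ci$net$reaction_ids)
  expect_equal(sum(blk$delta %in% model$row_i[[jin1]]), 2)
})

test_that("coupling creates t*(P+1) product variables with 3 rows each", {
  ci <- count_instance()
  for (P in 0:2) {
    enc <- fluxmod:::drug_encodings(ci$catalog, P)
    model <- fluxmod:::new_mip()
    primal <- build_primal_block(model, ci$net, ci$ref, ci$catalog, enc)
    dual <- build_dual_block(model, ci$net, ci$ref, ci$catalog, 100)
    before <- fluxmod:::n_vars(model)
    cpl <- build_duality_coupling(model, ci$net, ci$ref, ci$catalog, enc,
                                  primal, dual, 100)
    expect_equal(fluxmod:::n_vars(model) - before, 3 * (P + 1))
    expect_equal(unname(cpl$n_rows["linearization"]), 3L * 3L * (P + 1L))
    expect_equal(unname(cpl$n_rows["duality"]), 1L)
  }
  expect_error({
    model <- fluxmod:::new_mip()
    enc <- fluxmod:::drug_encodings(ci$catalog, 1)
    primal <- build_primal_block(model, ci$net, ci$ref, ci$catalog, enc)
    dual <- build_dual_block(model, ci$net, ci$ref, ci$catalog, 100)
    build_duality_coupling(model, ci$net, ci$ref, ci$catalog, enc,
                           primal, dual, -5)
  }, "positive")
})

test_that("big-M rows pin z to delta (x=1) and to 0 (x=0)", {
  # solve tiny LPs over the three linearization rows with x fixed
  for (xfix in c(0, 1)) {
    m <- fluxmod:::new_mip()
    delta <- fluxmod:::add_var(m, "delta", lb = 3, ub = 3)  # fixed delta=3
    z <- fluxmod:::add_var(m, "z", lb = 0, ub = 5, obj = 1)
    x <- fluxmod:::add_var(m, "x", lb = xfix, ub = xfix)
    fluxmod:::add_row(m, c(z, x), c(1, -5), ub = 0)
    fluxmod:::add_row(m, c(z, delta), c(1, -1), ub = 0)
    fluxmod:::add_row(m, c(delta, z, x), c(1, -1, 5), ub = 5)
    lo <- fluxmod:::solve_program(fluxmod:::mip_problem(m))
    m$var_obj[z] <- -1
    hi <- fluxmod:::solve_program(fluxmod:::mip_problem(m))
    expect_equal(lo$objective, if (xfix == 1) 3 else 0, tolerance = 1e-9)
    expect_equal(-hi$objective, if (xfix == 1) 3 else 0, tolerance = 1e-9)
  }
})

test_that("fixed-h inner primal and derived dual agree on every grid point", {
  fx <- fixture("superfluous-drug")
  cc <- canonical_ref(fx$network)
  H <- as.matrix(expand.grid(c(0, 0.5, 1), c(0, 0.25, 0.75, 1)))
  probs <- list()
  for (i in seq_len(nrow(H))) {
    probs[[2 * i - 1]] <- fluxmod:::inner_primal_problem(cc$net, cc$ref,
                                                         fx$catalog, H[i, ])
    probs[[2 * i]] <- fluxmod:::inner_dual_problem(cc$net, cc$ref,
                                                   fx$catalog, H[i, ])
  }
  res <- fluxmod:::solve_programs(probs)
  for (i in seq_len(nrow(H))) {
    primal <- res[[2 * i - 1]]; dual <- res[[2 * i]]
    expect_equal(primal$status, "optimal")
    expect_equal(dual$status, "optimal")
    expect_equal(primal$objective, -dual$objective, tolerance = 1e-9)
  }
})

test_that("delta_max estimates dominate the observed optimal duals", {
  fx <- fixture("chain")
  cc <- canonical_ref(fx$network)
  t_pairs <- nrow(fluxmod:::target_pairs(fx$catalog, cc$net))
  uni <- estimate_delta_max(cc$net, cc$ref, fx$catalog)
  expect_length(uni, t_pairs)
  expect_true(all(uni >= max(cc$net$upper_bounds)))
  smp <- estimate_delta_max(cc$net, cc$ref, fx$catalog, method = "sampled")
  # duals of the fixed-h inner LP over the whole grid stay below both bounds
  r <- length(cc$net$reaction_ids); m <- length(cc$net$metabolite_ids)
  probs <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(h)
    fluxmod:::inner_dual_problem(cc$net, cc$ref, fx$catalog, h))
  res <- fluxmod:::solve_programs(probs)
  for (re in res) {
    delta <- re$x[m + r + seq_len(t_pairs)]
    expect_true(all(delta <= uni + 1e-6))
    expect_true(all(delta <= smp + 1e-6))
  }
  # a delta_max that binds at the optimum is flagged on the solution
  sol <- solve_bilevel(cc$net, cc$ref, fx$catalog, "R_BIO", 0.5, P = 1,
                       delta_max = 2, validate = FALSE)
  expect_false(sol$delta_bound_ok)
  expect_equal(sol$side_effect, 10, tolerance = 1e-6)
  # an absurdly small delta_max cannot satisfy the strong-duality row at
  # all: the MILP is infeasible rather than silently wrong
  expect_error(solve_bilevel(cc$net, cc$ref, fx$catalog, "R_BIO", 0.5,
                             P = 1, delta_max = 1e-6, validate = FALSE),
               "no combination")
})

test_that("chain optimum: h=0.5 at P=1, forced full stop at P=0", {
  cc <- canonical_ref(make_chain())
  catalog <- chain_catalog()
  sol1 <- solve_bilevel(cc$net, cc$ref, catalog, "R_BIO", 0.5, P = 1)
  expect_equal(unname(sol1$h), 0.5)
  expect_equal(sol1$side_effect, 10, tolerance = 1e-6)
  expect_lte(sol1$duality_residual, 1e-6)
  expect_lte(sol1$v_mod, 0.5 * 10 + 1e-6)
  sol0 <- solve_bilevel(cc$net, cc$ref, catalog, "R_BIO", 0.5, P = 0)
  expect_equal(unname(sol0$h), 1)
  expect_equal(sol0$side_effect, 20, tolerance = 1e-6)
  # exhaustive oracle agrees on both grids
  for (P in 0:1) {
    ora <- exhaustive_oracle(cc$net, cc$ref, catalog, "R_BIO", 0.5, P = P)
    sol <- if (P == 0) sol0 else sol1
    expect_equal(sol$objective, ora$objective, tolerance = 1e-6)
  }
})

test_that("a drug with a dominated target set is left unused", {
  fx <- fixture("superfluous-drug")
  cc <- canonical_ref(fx$network)
  sol <- solve_bilevel(cc$net, cc$ref, fx$catalog, fx$mod_id, fx$tau,
                       P = fx$P)
  expect_equal(unname(sol$h), c(0, 0.75))
  expect_equal(sol$side_effect, 30, tolerance = 1e-6)
  ora <- exhaustive_oracle(cc$net, cc$ref, fx$catalog, fx$mod_id, fx$tau,
                           P = fx$P)
  expect_equal(sol$objective, ora$objective, tolerance = 1e-6)
  expect_equal(unname(ora$h), c(0, 0.75))
})

test_that("activation mode enforces v_mod >= tau * v_ut", {
  fx <- fixture("activation")
  cc <- canonical_ref(fx$network)
  sol <- solve_bilevel(cc$net, cc$ref, fx$catalog, fx$mod_id, fx$tau,
                       mode = "activate", P = fx$P)
  expect_equal(unname(sol$h), 0.5)
  expect_equal(sol$side_effect, 9, tolerance = 1e-6)
  expect_gte(sol$v_mod, 1.5 * 4 - 1e-6)
  expect_error(solve_bilevel(cc$net, cc$ref, fx$catalog, fx$mod_id, 0.5,
                             mode = "activate"), "tau > 1")
  expect_error(solve_bilevel(cc$net, cc$ref, fx$catalog, fx$mod_id, 1.5,
                             mode = "inhibit"), "tau < 1")
})

test_that("an uninfluential drug cannot inhibit the objective: infeasible", {
  fx <- fixture("diamond")
  cc <- canonical_ref(fx$network)
  expect_error(solve_bilevel(cc$net, cc$ref, fx$catalog, "R_BIO", 0.1),
               "no combination achieves the modulation target")
})

test_that("dose-response scheme restricts h to the experimental levels", {
  cc <- canonical_ref(make_chain())
  catalog <- drug_catalog("D1", list("R_UP"), list(c(0.3, 0.6)))
  # achievable h: {0, 0.3, 0.6, 1}; tau = 0.5 needs h >= 0.5 -> h = 0.6
  sol <- solve_bilevel(cc$net, cc$ref, catalog, "R_BIO", 0.5,
                       scheme = "dose")
  expect_equal(unname(sol$h), 0.6, tolerance = 1e-9)
  expect_equal(sol$side_effect, 12, tolerance = 1e-6)
  ora <- exhaustive_oracle(cc$net, cc$ref, catalog, "R_BIO", 0.5,
                           scheme = "dose")
  expect_equal(ora$objective, sol$objective, tolerance = 1e-6)
})
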