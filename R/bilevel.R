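# Single-level MILP reformulation of the bilevel drug-combination problem.
#
# Inner problem (h fixed): min sum(a) over
#   S v = 0                                  (duals mu, free)
#   v_j <= U_j                               (duals lambda_j >= 0)
#   v_i <= U_i (1 - h_k)  per (k, i in T_k)  (duals delta_p >= 0)
#   v_i - a_i <= +v_ut_i                     (duals alpha_i >= 0)
#   -v_i - a_i <= -v_ut_i                    (duals beta_i >= 0)
#   v, a >= 0
#
# Deriving the Lagrangian dual of this standard form gives the dual
# constraints
#   sum_i S_ij mu_i + lambda_j + sum_{p: target(p)=j} delta_p
#     + alpha_j - beta_j >= 0          and   alpha_j + beta_j <= 1
# and the dual objective -[ sum_j U_j lambda_j
#   + sum_p U_{i(p)} (1 - h_{k(p)}) delta_p + sum_j (alpha_j - beta_j) v_ut_j ].
# Strong duality (primal objective = dual objective) is therefore the row
#   sum_i a_i + sum_j U_j lambda_j + sum_p U_{i(p)} (delta_p - z_p)
#     + sum_j (alpha_j - beta_j) v_ut_j = 0,
# where z_p = delta_p h_k is expanded over the Boolean dosage variables and
# linearized exactly with big-M rows (delta_p is bounded by delta_max_p).

#' Build the primal inner-problem constraint block
#'
#' Appends to `model` the flux and deviation variables and the steady-state,
#' bound, inhibition (with `h_k` expanded over the Boolean dosage
#' variables) and absolute-value rows: `m + r + t + 2r` rows in total,
#' where `t` is the number of (drug, target) pairs.
#'
#' @param model A model builder (internal) to append to.
#' @param net Canonical [metabolic_network()].
#' @param v_ut Untreated fluxes (vector or [fba_reference()] result).
#' @param catalog A [drug_catalog()].
#' @param encodings Per-drug encodings from `drug_encodings()`.
#' @return Invisibly, a list with the variable indices (`v`, `a`, `x`) and
#'   row counts per block.
#' @keywords internal
#' @export
build_primal_block <- function(model, net, v_ut, catalog, encodings) {
  v_ut <- ref_fluxes(v_ut)
  r <- n_reactions(net); m <- n_metabolites(net)
  U <- net$upper_bounds
  pairs <- target_pairs(catalog, net)
  v <- add_vars(model, paste0("v[", net$reaction_ids, "]"), lb = 0, ub = U)
  a <- add_vars(model, paste0("a[", net$reaction_ids, "]"), lb = 0, ub = Inf,
                obj = 1)
  x <- lapply(seq_len(n_drugs(catalog)), function(k) {
    nk <- length(encodings[[k]]$weights)
    add_vars(model, paste0("x[", catalog$drug_ids[k], ",", seq_len(nk) - 1L, "]"),
             lb = 0, ub = 1, integer = TRUE)
  })
  for (i in seq_len(m))                                      # (steady state)
    add_row(model, v, net$stoich[i, ], lb = 0, ub = 0,
            name = paste0("steady[", net$metabolite_ids[i], "]"))
  for (j in seq_len(r))                                      # (v <= U)
    add_row(model, v[j], 1, ub = U[j], name = paste0("ub[", j, "]"))
  if (nrow(pairs))                                           # (inhibition)
    for (p in seq_len(nrow(pairs))) {
      k <- pairs$drug[p]; i <- pairs$target[p]
      add_row(model, c(v[i], x[[k]]), c(1, U[i] * encodings[[k]]$weights),
              ub = U[i], name = paste0("inh[", p, "]"))
    }
  for (j in seq_len(r))                                      # (abs +)
    add_row(model, c(v[j], a[j]), c(1, -1), ub = v_ut[j],
            name = paste0("absp[", j, "]"))
  for (j in seq_len(r))                                      # (abs -)
    add_row(model, c(v[j], a[j]), c(-1, -1), ub = -v_ut[j],
            name = paste0("absm[", j, "]"))
  invisible(list(v = v, a = a, x = x, pairs = pairs,
                 n_rows = c(steady = m, ub = r, inhibition = nrow(pairs),
                            abs = 2L * r)))
}

#' Build the dual constraint block
#'
#' Appends the dual variables (`mu` free, `lambda`, `delta`, `alpha`,
#' `beta` non-negative) and the `2r` dual rows: for every reaction `j`,
#' `S'_j mu + lambda_j + sum(delta over pairs targeting j) + alpha_j -
#' beta_j >= 0` and `alpha_j + beta_j <= 1`. The sign conventions come
#' from an explicit derivation of the inner problem's Lagrangian dual
#' (see the header of this file and the methods vignette).
#'
#' @inheritParams build_primal_block
#' @param delta_max Per-pair upper bounds for the `delta` duals (big-M).
#' @return Invisibly, variable indices (`mu`, `lambda`, `delta`, `alpha`,
#'   `beta`) and row counts.
#' @keywords internal
#' @export
build_dual_block <- function(model, net, v_ut, catalog, delta_max = Inf) {
  r <- n_reactions(net); m <- n_metabolites(net)
  pairs <- target_pairs(catalog, net)
  t_pairs <- nrow(pairs)
  delta_max <- rep_len(delta_max, t_pairs)
  mu <- add_vars(model, paste0("mu[", net$metabolite_ids, "]"),
                 lb = -Inf, ub = Inf)
  lambda <- add_vars(model, paste0("lambda[", seq_len(r), "]"), lb = 0, ub = Inf)
  delta <- if (t_pairs) add_vars(model, paste0("delta[", seq_len(t_pairs), "]"),
                                 lb = 0, ub = delta_max) else integer(0)
  alpha <- add_vars(model, paste0("alpha[", seq_len(r), "]"), lb = 0, ub = 1)
  beta <- add_vars(model, paste0("beta[", seq_len(r), "]"), lb = 0, ub = 1)
  for (j in seq_len(r)) {
    p_j <- if (t_pairs) which(pairs$target == j) else integer(0)
    add_row(model,
            c(mu, lambda[j], delta[p_j], alpha[j], beta[j]),
            c(net$stoich[, j], 1, rep(1, length(p_j)), 1, -1),
            lb = 0, name = paste0("dual[", j, "]"))
  }
  for (j in seq_len(r))
    add_row(model, c(alpha[j], beta[j]), c(1, 1), ub = 1,
            name = paste0("dualab[", j, "]"))
  invisible(list(mu = mu, lambda = lambda, delta = delta, alpha = alpha,
                 beta = beta, pairs = pairs, delta_max = delta_max,
                 n_rows = c(dual = r, dual_ab = r)))
}

#' Build the strong-duality coupling with big-M linearization
#'
#' Introduces one product variable `z[p,n] = delta_p * x_{k(p),n}` per
#' ((drug,target) pair, Boolean) combination, each with the exact
#' linearization rows `z <= delta_max * x`, `z <= delta`,
#' `z >= delta - delta_max (1 - x)` (plus the bound `0 <= z <= delta_max`),
#' then writes the strong-duality equality row using
#' `z_p = sum_n w_n z[p,n]` in place of `delta_p h_k`. Also adds the
#' encoding-validity rows: the binary-expansion anti-redundancy constraint
#' `P x_{k,0} <= sum_{j>=1} x_{k,j}` (for `P >= 1`) and the
#' prefix-of-ones chain for dose-response drugs.
#'
#' @inheritParams build_primal_block
#' @param primal,dual Blocks returned by [build_primal_block()] and
#'   [build_dual_block()].
#' @param big_m_values Per-pair `delta_max` bounds (positive, finite).
#' @return Invisibly, the `z` variable index matrix-like list and row counts.
#' @keywords internal
#' @export
build_duality_coupling <- function(model, net, v_ut, catalog, encodings,
                                   primal, dual, big_m_values) {
  v_ut <- ref_fluxes(v_ut)
  pairs <- primal$pairs
  t_pairs <- nrow(pairs)
  big_m_values <- rep_len(big_m_values, max(t_pairs, 1L))
  if (t_pairs && any(!is.finite(big_m_values) | big_m_values <= 0))
    stop("big-M values (delta_max) must be positive and finite")
  U <- net$upper_bounds
  r <- n_reactions(net)
  z <- vector("list", t_pairs)
  n_lin <- 0L
  for (p in seq_len(t_pairs)) {
    k <- pairs$drug[p]
    w <- encodings[[k]]$weights
    dmax <- big_m_values[p]
    zp <- add_vars(model, paste0("z[", p, ",", seq_along(w) - 1L, "]"),
                   lb = 0, ub = dmax)
    for (n in seq_along(w)) {
      xkn <- primal$x[[k]][n]
      add_row(model, c(zp[n], xkn), c(1, -dmax), ub = 0)          # z <= M x
      add_row(model, c(zp[n], dual$delta[p]), c(1, -1), ub = 0)   # z <= delta
      add_row(model, c(dual$delta[p], zp[n], xkn), c(1, -1, dmax),
              ub = dmax)                     # delta - z <= M (1 - x)
      n_lin <- n_lin + 3L
    }
    z[[p]] <- zp
  }
  # strong-duality equality row
  idx <- c(primal$a, dual$lambda, dual$alpha, dual$beta)
  coef <- c(rep(1, r), U, v_ut, -v_ut)
  if (t_pairs) {
    idx <- c(idx, dual$delta)
    coef <- c(coef, U[pairs$target])
    for (p in seq_len(t_pairs)) {
      w <- encodings[[pairs$drug[p]]]$weights
      idx <- c(idx, z[[p]])
      coef <- c(coef, -U[pairs$target[p]] * w)
    }
  }
  add_row(model, idx, coef, lb = 0, ub = 0, name = "strong_duality")
  # encoding-validity rows
  n_enc <- 0L
  for (k in seq_len(n_drugs(catalog))) {
    enc <- encodings[[k]]
    xk <- primal$x[[k]]
    if (enc$scheme == "binary" && enc$P >= 1L) {
      add_row(model, xk, c(enc$P, rep(-1, enc$P)), ub = 0,
              name = paste0("redund[", k, "]"))
      n_enc <- n_enc + 1L
    } else if (enc$scheme == "dose") {
      for (n in seq_along(xk)[-1L]) {
        add_row(model, c(xk[n], xk[n - 1L]), c(1, -1), ub = 0)
        n_enc <- n_enc + 1L
      }
    }
  }
  invisible(list(z = z, n_rows = c(linearization = n_lin, duality = 1L,
                                   encoding = n_enc)))
}

#' Upper bounds for the inhibition duals (big-M values)
#'
#' The `delta_max` bounds must dominate the optimal duals of the inner LP
#' for the returned treatment, otherwise the strong-duality row cuts off
#' the true optimum.
#'
#' `method = "uniform"` returns the conservative default
#' `max(1, kappa * max(U))` for every pair. `method = "sampled"` solves
#' the explicit dual LP at a sample of extreme inhibition vectors (no
#' drug, each drug alone at full dose, all drugs at full dose) and
#' returns 10x the largest observed `delta` per pair, floored at the
#' uniform default / kappa. Either way, [solve_bilevel()] re-validates
#' the returned optimum by an independent MOMA solve and enlarges the
#' bounds if the validation fails.
#'
#' @inheritParams build_primal_block
#' @param method `"uniform"` or `"sampled"`.
#' @param kappa Scale factor of the uniform bound (default 10).
#' @return Numeric vector, one bound per (drug, target) pair.
#' @export
estimate_delta_max <- function(net, v_ut, catalog,
                               method = c("uniform", "sampled"), kappa = 10) {
  method <- match.arg(method)
  t_pairs <- nrow(target_pairs(catalog, net))
  base <- max(1, kappa * max(net$upper_bounds))
  if (method == "uniform" || t_pairs == 0L)
    return(rep(base, t_pairs))
  d <- n_drugs(catalog)
  hs <- c(list(rep(0, d)),
          lapply(seq_len(d), function(k) { h <- rep(0, d); h[k] <- 1; h }),
          list(rep(1, d)))
  probs <- lapply(hs, function(h) inner_dual_problem(net, v_ut, catalog, h))
  res <- solve_programs(probs)
  dmax <- rep(base / kappa, t_pairs)
  r <- n_reactions(net); m <- n_metabolites(net)
  for (re in res) {
    if (re$status != "optimal") next
    delta <- re$x[m + r + seq_len(t_pairs)]
    dmax <- pmax(dmax, delta)
  }
  pmax(10 * dmax, 1)
}

# Explicit inner primal LP at fixed h (variables v, a).
inner_primal_problem <- function(net, v_ut, catalog, h) {
  bw <- apply_inhibition(net, catalog, h)
  moma_l1_problem(net, ref_fluxes(v_ut), bw$ub_eff)
}

# Explicit dual LP of the inner problem at fixed h.
# Variables: (mu_1..mu_m, lambda_1..lambda_r, delta_1..delta_t,
#             alpha_1..alpha_r, beta_1..beta_r).
inner_dual_problem <- function(net, v_ut, catalog, h) {
  v_ut <- ref_fluxes(v_ut)
  r <- n_reactions(net); m <- n_metabolites(net)
  U <- net$upper_bounds
  pairs <- target_pairs(catalog, net)
  t_pairs <- nrow(pairs)
  nv <- m + r + t_pairs + 2L * r
  A <- matrix(0, 2L * r, nv)
  for (j in seq_len(r)) {
    A[j, seq_len(m)] <- net$stoich[, j]
    A[j, m + j] <- 1
    if (t_pairs) {
      pj <- which(pairs$target == j)
      A[j, m + r + pj] <- 1
    }
    A[j, m + r + t_pairs + j] <- 1          # alpha_j
    A[j, m + r + t_pairs + r + j] <- -1     # beta_j
    A[r + j, m + r + t_pairs + j] <- 1
    A[r + j, m + r + t_pairs + r + j] <- 1
  }
  # maximize -(U'lambda + sum U (1-h) delta + (alpha-beta)'v_ut)
  # as min of the negated expression
  obj <- c(numeric(m), U,
           if (t_pairs) U[pairs$target] * (1 - h[pairs$drug]) else numeric(0),
           v_ut, -v_ut)
  lp_problem(obj, A,
             rlb = c(rep(0, r), rep(-Inf, r)),
             rub = c(rep(Inf, r), rep(1, r)),
             lb = c(rep(-Inf, m), numeric(nv - m)),
             ub = rep(Inf, nv))
}

#' Primal/dual agreement of the inner problem at a fixed treatment
#'
#' Solves the inner L1-MOMA LP and its explicitly derived dual at a fixed
#' inhibition vector `h` and reports both optima and their gap. Used to
#' certify the sign conventions of the duality reformulation.
#'
#' @inheritParams build_primal_block
#' @param h Inhibition vector in `[0,1]^d`.
#' @return List with `primal`, `dual` (both on the minimization scale of
#'   the inner problem) and `gap = |primal - dual|`.
#' @export
inner_duality_gap <- function(net, v_ut, catalog, h) {
  res <- solve_programs(list(inner_primal_problem(net, v_ut, catalog, h),
                             inner_dual_problem(net, v_ut, catalog, h)))
  if (res[[1L]]$status != "optimal" || res[[2L]]$status != "optimal")
    stop("inner primal/dual solve failed: ", res[[1L]]$status, "/",
         res[[2L]]$status)
  primal <- res[[1L]]$objective
  dual <- -res[[2L]]$objective   # dual LP was minimized in negated form
  list(primal = primal, dual = dual, gap = abs(primal - dual))
}

#' Solve the bilevel drug-combination problem as a single MILP
#'
#' Finds the dosage vector `h` (on the encoding's achievable grid) whose
#' L1-MOMA response modulates the objective reaction past the threshold
#' (`v_mod <= tau * v_ut_mod` in `"inhibit"` mode, `>=` in `"activate"`
#' mode) with minimal side effect `||v_tr - v_ut||_1`. A small penalty
#' `b * sum_k h_k` discards superfluous drugs among side-effect-equivalent
#' optima. The returned solution is re-validated by an independent
#' [moma_l1()] solve at the decoded `h`; if the validation fails (a sign
#' of too-small `delta_max`), the `delta_max` bounds are enlarged tenfold
#' and the MILP is re-solved, up to `max_retries` times.
#'
#' @inheritParams build_primal_block
#' @param mod_id Objective (modulated) reaction id in the canonical network.
#' @param tau Modulation threshold: `0 <= tau < 1` for `"inhibit"`,
#'   `tau > 1` for `"activate"`.
#' @param mode `"inhibit"` or `"activate"`.
#' @param P Dosage precision (binary-expansion scheme).
#' @param scheme `"binary"` or `"dose"` (see `drug_encodings()`).
#' @param b Anti-overselection weight (default `1e-3`).
#' @param delta_max Optional per-pair dual bounds; default
#'   [estimate_delta_max()] with `method = "uniform"`.
#' @param mip_rel_gap Relative MILP gap (default 0: exact).
#' @param time_limit Optional solver time limit in seconds.
#' @param validate Re-validate by an independent MOMA solve (default TRUE).
#' @param max_retries Big-M enlargement retries on failed validation.
#' @return A `treatment_solution`: `h`, Boolean dosages `x`, `v_tr`,
#'   `side_effect`, `objective`, `duality_residual`, `status`, plus the
#'   run parameters.
#' @export
solve_bilevel <- function(net, v_ut, catalog, mod_id, tau,
                          mode = c("inhibit", "activate"), P = 1,
                          scheme = c("binary", "dose"), b = 1e-3,
                          delta_max = NULL, mip_rel_gap = 0,
                          time_limit = NULL, validate = TRUE,
                          max_retries = 2) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  stopifnot(net$canonical)
  validate_catalog(catalog, net)
  jmod <- match(mod_id, net$reaction_ids)
  if (is.na(jmod)) stop("objective reaction not in network: ", mod_id)
  if (mode == "inhibit" && !(tau >= 0 && tau < 1))
    stop("inhibit mode requires 0 <= tau < 1")
  if (mode == "activate" && !(tau > 1))
    stop("activate mode requires tau > 1")
  v_ut <- ref_fluxes(v_ut)
  encodings <- drug_encodings(catalog, P, scheme)
  if (is.null(delta_max))
    delta_max <- estimate_delta_max(net, v_ut, catalog)
  attempt <- 0L
  repeat {
    sol <- solve_bilevel_once(net, v_ut, catalog, jmod, tau, mode, P, scheme,
                              b, encodings, delta_max, mip_rel_gap, time_limit)
    if (!validate || sol$status != "optimal") break
    check <- moma_l1(net, v_ut, apply_inhibition(net, catalog, sol$h))
    mismatch <- abs(check$side_effect - sol$side_effect) >
      1e-6 * max(1, sol$side_effect)
    if (!mismatch) break
    attempt <- attempt + 1L
    if (attempt > max_retries)
      stop("bilevel validation failed: MILP side effect ", sol$side_effect,
           " vs MOMA re-solve ", check$side_effect,
           "; delta_max bounds too small even after retries")
    warning("bilevel validation mismatch; enlarging delta_max bounds (x10)")
    delta_max <- delta_max * 10
  }
  sol
}

solve_bilevel_once <- function(net, v_ut, catalog, jmod, tau, mode, P, scheme,
                               b, encodings, delta_max, mip_rel_gap,
                               time_limit) {
  model <- new_mip()
  primal <- build_primal_block(model, net, v_ut, catalog, encodings)
  dual <- build_dual_block(model, net, v_ut, catalog, delta_max)
  coupling <- build_duality_coupling(model, net, v_ut, catalog, encodings,
                                     primal, dual, delta_max)
  # outer modulation constraint (7i)
  thr <- tau * v_ut[jmod]
  if (mode == "inhibit")
    add_row(model, primal$v[jmod], 1, ub = thr, name = "modulation")
  else
    add_row(model, primal$v[jmod], 1, lb = thr, name = "modulation")
  # anti-overselection term b * sum_k h_k on the Booleans
  for (k in seq_len(n_drugs(catalog)))
    model$var_obj[primal$x[[k]]] <- b * encodings[[k]]$weights
  opts <- list(mip_rel_gap = mip_rel_gap)
  if (!is.null(time_limit)) opts$time_limit <- time_limit
  res <- solve_program(mip_problem(model, opts))
  if (res$status == "infeasible")
    stop("no combination achieves the modulation target (MILP infeasible; ",
         "mod=", net$reaction_ids[jmod], ", tau=", tau, ", mode=", mode, ")")
  if (res$status == "limit")
    stop("MILP solver hit its limit before proving optimality",
         if (!is.null(res$objective) && is.finite(res$objective))
           paste0("; incumbent objective ", res$objective) else "")
  if (res$status != "optimal")
    stop("MILP solve failed (status ", res$status, "): ", res$message)
  r <- n_reactions(net)
  xs <- lapply(seq_len(n_drugs(catalog)), function(k)
    round(res$x[primal$x[[k]]]))
  h <- vapply(seq_along(xs), function(k) decode_h(encodings[[k]], xs[[k]]), 0)
  h <- pmin(pmax(h, 0), 1)
  v_tr <- stats::setNames(res$x[primal$v], net$reaction_ids)
  a <- res$x[primal$a]
  lambda <- res$x[dual$lambda]
  alpha <- res$x[dual$alpha]
  beta <- res$x[dual$beta]
  pairs <- primal$pairs
  t_pairs <- nrow(pairs)
  delta <- if (t_pairs) res$x[dual$delta] else numeric(0)
  dual_obj <- -(sum(net$upper_bounds * lambda) +
                  (if (t_pairs)
                    sum(net$upper_bounds[pairs$target] * delta *
                          (1 - h[pairs$drug])) else 0) +
                  sum((alpha - beta) * v_ut))
  primal_obj <- sum(a)
  se <- side_effect(v_tr, v_ut)
  # dual certificates are non-unique, so a delta at its bound is not by
  # itself an error; the flag is reported and the re-solve validation in
  # solve_bilevel() is the authoritative check
  delta_bound_ok <- !(t_pairs && any(delta > 0.99 * delta_max))
  structure(list(h = stats::setNames(h, catalog$drug_ids),
                 booleans = stats::setNames(xs, catalog$drug_ids),
                 v_tr = v_tr,
                 side_effect = se,
                 objective = res$objective,
                 duality_residual = abs(primal_obj - dual_obj) /
                   max(1, abs(primal_obj)),
                 status = res$status,
                 mode = mode, tau = tau, P = as.integer(P), scheme = scheme,
                 b = b, mod_id = net$reaction_ids[jmod],
                 delta_max = delta_max, delta_bound_ok = delta_bound_ok,
                 v_mod = unname(v_tr[jmod]),
                 method = "bilevel-milp",
                 tolerances = c(integrality = 1e-6, feasibility = 1e-9,
                                mip_rel_gap = mip_rel_gap)),
            class = "treatment_solution")
}

#' @export
print.treatment_solution <- function(x, ...) {
  cat(sprintf("<treatment_solution (%s, %s): mod=%s tau=%g P=%d>\n",
              x$method, x$mode, x$mod_id, x$tau, x$P))
  on <- x$h > 1e-9
  cat("  h:", if (any(on))
    paste0(names(x$h)[on], "=", signif(x$h[on], 6), collapse = ", ")
    else "(no drug)", "\n")
  cat(sprintf("  side effect: %.6g;  v_mod: %.6g;  status: %s\n",
              x$side_effect, x$v_mod, x$status))
  invisible(x)
}

#' Export the assembled MILP in LP format
#'
#' Writes the single-level MILP (without solving it) in CPLEX LP format for
#' audit with an external solver.
#'
#' @inheritParams solve_bilevel
#' @param path Output `.lp` file.
#' @return `path`, invisibly.
#' @export
write_bilevel_lp <- function(net, v_ut, catalog, mod_id, tau,
                             mode = c("inhibit", "activate"), P = 1,
                             scheme = c("binary", "dose"), b = 1e-3,
                             delta_max = NULL, path) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  v_ut <- ref_fluxes(v_ut)
  jmod <- match(mod_id, net$reaction_ids)
  if (is.na(jmod)) stop("objective reaction not in network: ", mod_id)
  encodings <- drug_encodings(catalog, P, scheme)
  if (is.null(delta_max)) delta_max <- estimate_delta_max(net, v_ut, catalog)
  model <- new_mip()
  primal <- build_primal_block(model, net, v_ut, catalog, encodings)
  dual <- build_dual_block(model, net, v_ut, catalog, delta_max)
  build_duality_coupling(model, net, v_ut, catalog, encodings, primal, dual,
                         delta_max)
  thr <- tau * v_ut[jmod]
  if (mode == "inhibit") add_row(model, primal$v[jmod], 1, ub = thr)
  else add_row(model, primal$v[jmod], 1, lb = thr)
  for (k in seq_len(n_drugs(catalog)))
    model$var_obj[primal$x[[k]]] <- b * encodings[[k]]$weights
  write_lp_format(model, path)
}

# Minimal CPLEX-LP-format writer (names sanitized to solver-safe tokens).
write_lp_format <- function(model, path) {
  nm <- gsub("[^A-Za-z0-9_]", "_", model$var_name)
  nm <- make.unique(nm, sep = "_")
  term <- function(idx, coef) paste(
    sprintf("%+.17g %s", coef, nm[idx]), collapse = " ")
  lines <- c("Minimize", paste(" obj:",
                               term(which(model$var_obj != 0),
                                    model$var_obj[model$var_obj != 0])),
             "Subject To")
  for (k in seq_len(n_rows(model))) {
    lhs <- term(model$row_i[[k]], model$row_x[[k]])
    lb <- model$row_lb[k]; ub <- model$row_ub[k]
    rn <- sprintf("c%d", k)
    if (is.finite(lb) && is.finite(ub) && lb == ub)
      lines <- c(lines, sprintf(" %s: %s = %.17g", rn, lhs, lb))
    else {
      if (is.finite(ub)) lines <- c(lines, sprintf(" %s: %s <= %.17g", rn, lhs, ub))
      if (is.finite(lb)) lines <- c(lines, sprintf(" %sl: %s >= %.17g", rn, lhs, lb))
    }
  }
  lines <- c(lines, "Bounds")
  for (j in seq_len(n_vars(model))) {
    lb <- model$var_lb[j]; ub <- model$var_ub[j]
    lines <- c(lines, sprintf(" %s %s %s",
                              if (is.finite(lb)) sprintf("%.17g <=", lb) else "-inf <=",
                              nm[j],
                              if (is.finite(ub)) sprintf("<= %.17g", ub) else ""))
  }
  if (any(model$var_int))
    lines <- c(lines, "Binaries", paste("", paste(nm[model$var_int],
                                                  collapse = " ")))
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}
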