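# Downstream analyses: exhaustive-search oracle, nonlinearity (synergy)
# index, drug-interaction surfaces, and the all-reactions screening with
# most-stringent-threshold deduplication.

#' Exhaustive search over the dosage grid
#'
#' Enumerates every achievable inhibition vector `h` on the per-drug
#' dosage grid, evaluates L1-MOMA for each, keeps those for which some
#' inner-optimal flux vector satisfies the modulation constraint, and
#' returns the minimizer of `side_effect + b * sum(h)`. This is the
#' brute-force reference against which [solve_bilevel()] is checked;
#' its cost is `prod(grid sizes)` LP solves ("the cost of an exhaustive
#' search over all possible drug combinations and dosages").
#'
#' Because the L1 inner optimum can be non-unique, feasibility of a grid
#' point is decided optimistically (as the MILP does): a second LP asks
#' whether the inner-optimal face contains a point meeting the threshold.
#'
#' @inheritParams solve_bilevel
#' @param cap Maximum number of grid points (default `2e5`).
#' @return A `treatment_solution` with `method = "exhaustive"` and
#'   attribute `n_evaluations`, or an infeasible marker (class
#'   `infeasible_treatment`) when no grid point qualifies.
#' @export
exhaustive_oracle <- function(net, v_ut, catalog, mod_id, tau,
                              mode = c("inhibit", "activate"), P = 1,
                              scheme = c("binary", "dose"), b = 1e-3,
                              cap = 2e5) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  stopifnot(net$canonical)
  validate_catalog(catalog, net)
  v_ut <- ref_fluxes(v_ut)
  jmod <- match(mod_id, net$reaction_ids)
  if (is.na(jmod)) stop("objective reaction not in network: ", mod_id)
  encodings <- drug_encodings(catalog, P, scheme)
  grids <- lapply(encodings, `[[`, "grid")
  n_grid <- prod(lengths(grids))
  if (n_grid > cap)
    stop("grid has ", n_grid, " points, above cap ", cap,
         "; reduce P or the number of drugs")
  H <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(H) <- catalog$drug_ids
  ub_list <- lapply(seq_len(nrow(H)), function(g)
    apply_inhibition(net, catalog, H[g, ])$ub_eff)
  inner <- moma_l1_batch(net, v_ut, ub_list)
  opt_val <- vapply(inner, function(s) if (is.null(s)) NA_real_
                    else s$side_effect, 0)
  thr <- tau * v_ut[jmod]
  solved <- which(!is.na(opt_val))
  probs <- lapply(solved, function(g)
    mod_extreme_problem(net, v_ut, ub_list[[g]], jmod, opt_val[g],
                        maximize = (mode == "activate")))
  ext <- solve_programs(probs)
  feas <- rep(FALSE, nrow(H))
  v_cand <- vector("list", nrow(H))
  for (s in seq_along(solved)) {
    g <- solved[s]
    if (ext[[s]]$status != "optimal") next
    vmod <- if (mode == "activate") -ext[[s]]$objective else ext[[s]]$objective
    tol <- 1e-7 * max(1, abs(thr))
    ok <- if (mode == "inhibit") vmod <= thr + tol else vmod >= thr - tol
    feas[g] <- ok
    if (ok) v_cand[[g]] <- ext[[s]]$x[seq_len(n_reactions(net))]
  }
  n_eval <- nrow(H)
  if (!any(feas)) {
    return(structure(list(mod_id = net$reaction_ids[jmod], tau = tau,
                          mode = mode, P = as.integer(P),
                          status = "infeasible", method = "exhaustive",
                          n_evaluations = n_eval),
                     class = "infeasible_treatment"))
  }
  objective <- opt_val + b * rowSums(H)
  objective[!feas] <- Inf
  best <- min(objective)
  cand <- which(objective <= best + 1e-12 * max(1, abs(best)))
  # deterministic tie-break: lexicographically smallest h
  if (length(cand) > 1L)
    cand <- cand[do.call(order, as.data.frame(H[cand, , drop = FALSE]))]
  g <- cand[1L]
  v_tr <- stats::setNames(v_cand[[g]], net$reaction_ids)
  structure(list(h = stats::setNames(H[g, ], catalog$drug_ids),
                 v_tr = v_tr,
                 side_effect = opt_val[g],
                 objective = objective[g],
                 status = "optimal",
                 mode = mode, tau = tau, P = as.integer(P), scheme = scheme,
                 b = b, mod_id = net$reaction_ids[jmod],
                 v_mod = unname(v_tr[jmod]),
                 method = "exhaustive",
                 n_evaluations = n_eval),
            class = "treatment_solution")
}

# LP: minimize (or maximize) v_mod over the inner-optimal face
# {S v = 0, bounds, a >= |v - v_ut|, sum(a) <= opt}.
mod_extreme_problem <- function(net, v_ut, ub_eff, jmod, opt, maximize) {
  r <- n_reactions(net); m <- n_metabolites(net)
  base <- moma_l1_problem(net, v_ut, ub_eff)
  obj <- numeric(2L * r)
  obj[jmod] <- if (maximize) -1 else 1
  base$c <- obj
  # append sum(a) <= opt (small slack for LP tolerance)
  k <- length(base$A$x)
  base$A$i <- c(base$A$i, rep.int(base$A$nrow, r))
  base$A$j <- c(base$A$j, r + seq_len(r) - 1L)
  base$A$x <- c(base$A$x, rep(1, r))
  base$A$nrow <- base$A$nrow + 1L
  base$rlb <- c(base$rlb, -INF_SENTINEL)
  base$rub <- c(base$rub, opt + 1e-9 * max(1, opt))
  base
}

#' Nonlinearity (synergy) index of a drug combination
#'
#' Scaled deviation of the combined effect on the modulated flux from the
#' linear superposition of the single-drug effects:
#' `eta = (sum_k single_k - (d-1) v_ut_mod - combined) /
#' (v_ut_mod - combined)`. `eta = 0` means additive (linear) behaviour,
#' `eta > 0` synergistic deviation. When the combined treatment leaves
#' the modulated flux unchanged the index is undefined and `NA` is
#' returned.
#'
#' @param v_ut_mod Untreated flux of the modulated reaction.
#' @param single_effects Per-drug modulated fluxes `v_mod_tr(0,..,h_k,..,0)`.
#' @param combined Modulated flux under the full combination.
#' @param tol Relative tolerance deciding the undefined case.
#' @return The index value, or `NA_real_` when undefined.
#' @export
nonlinearity_index <- function(v_ut_mod, single_effects, combined,
                               tol = 1e-9) {
  d <- length(single_effects)
  if (d < 1L) stop("need at least one single-drug effect")
  denom <- v_ut_mod - combined
  if (abs(denom) <= tol * max(1, abs(v_ut_mod))) return(NA_real_)
  (sum(single_effects) - (d - 1) * v_ut_mod - combined) / denom
}

# eta for a full inhibition vector h: singles and combined evaluated by
# MOMA (batched). Returns NA when undefined.
#
# The L1 inner optimum can leave v_mod undetermined (degenerate optimal
# face). `extreme = "min"`/`"max"` determinizes every evaluation at the
# corresponding extreme of the optimal face (the inner optimum consistent
# with an inhibition/activation treatment); "none" uses the solver's
# vertex as-is (the raw surface convention).
eta_for_h <- function(net, v_ut, catalog, jmod, h, norm = "L1",
                      extreme = c("none", "min", "max")) {
  extreme <- match.arg(extreme)
  v_ut <- ref_fluxes(v_ut)
  d <- n_drugs(catalog)
  singles_h <- lapply(seq_len(d), function(k) { s <- rep(0, d); s[k] <- h[k]; s })
  ub_list <- c(lapply(singles_h, function(s)
    apply_inhibition(net, catalog, s)$ub_eff),
    list(apply_inhibition(net, catalog, h)$ub_eff))
  sols <- if (norm == "L2") moma_l2_batch(net, v_ut, ub_list)
  else moma_l1_batch(net, v_ut, ub_list)
  if (any(vapply(sols, is.null, TRUE))) return(NA_real_)
  vmods <- vapply(sols, function(s) unname(s$v_tr[jmod]), 0)
  if (extreme != "none" && norm == "L1") {
    probs <- lapply(seq_along(ub_list), function(i)
      mod_extreme_problem(net, v_ut, ub_list[[i]], jmod,
                          sols[[i]]$side_effect,
                          maximize = (extreme == "max")))
    ext <- solve_programs(probs)
    if (any(vapply(ext, `[[`, "", "status") != "optimal")) return(NA_real_)
    vmods <- vapply(ext, function(e)
      if (extreme == "max") -e$objective else e$objective, 0)
  }
  nonlinearity_index(unname(v_ut[jmod]), vmods[seq_len(d)], vmods[d + 1L])
}

#' Drug-interaction surface for a pair of drugs
#'
#' Sweeps the dosages of two drugs over the achievable grid (binary
#' expansion at precision `P`, so a `(2^P+1) x (2^P+1)` grid), holding the
#' remaining drugs at a fixed background, and records for every cell the
#' percentage of the untreated modulated flux that survives
#' (`100 * v_mod_tr / v_mod_ut`) and the nonlinearity index
#' [nonlinearity_index()]. MOMA is evaluated in the requested norm
#' (`"L1"` as in the single-level formulation, `"L2"` as the smooth
#' cross-check). Cells whose solve fails are `NA` (masked).
#'
#' @inheritParams solve_bilevel
#' @param drug_a,drug_b Distinct drug ids.
#' @param background_h Named or positional inhibition levels of the
#'   remaining drugs (default all 0).
#' @param norm `"L1"` or `"L2"`.
#' @return An `interaction_surface`: `grid_a`, `grid_b`, `flux_pct`,
#'   `eta`, ids and the background.
#' @export
interaction_surface <- function(net, v_ut, catalog, mod_id, drug_a, drug_b,
                                background_h = NULL, P = 4,
                                norm = c("L1", "L2")) {
  norm <- match.arg(norm)
  stopifnot(net$canonical)
  v_ut <- ref_fluxes(v_ut)
  ka <- match(drug_a, catalog$drug_ids)
  kb <- match(drug_b, catalog$drug_ids)
  if (is.na(ka) || is.na(kb))
    stop("unknown drug id: ", paste(c(drug_a, drug_b)[is.na(c(ka, kb))],
                                    collapse = ", "))
  if (ka == kb) stop("drug_a and drug_b must differ")
  jmod <- match(mod_id, net$reaction_ids)
  if (is.na(jmod)) stop("objective reaction not in network: ", mod_id)
  d <- n_drugs(catalog)
  bg <- rep(0, d)
  if (!is.null(background_h)) {
    if (!is.null(names(background_h))) {
      idx <- match(names(background_h), catalog$drug_ids)
      if (anyNA(idx)) stop("unknown drug in background_h")
      bg[idx] <- as.numeric(background_h)
    } else bg <- rep_len(as.numeric(background_h), d)
  }
  bg[c(ka, kb)] <- 0
  grid <- (0:2^P) / 2^P
  ng <- length(grid)
  cells <- expand.grid(a = seq_len(ng), b = seq_len(ng))
  mk_h <- function(ha, hb) { h <- bg; h[ka] <- ha; h[kb] <- hb; h }
  # one batch: all cells, then singles for every drug at its active level
  ub_cells <- lapply(seq_len(nrow(cells)), function(i)
    apply_inhibition(net, catalog,
                     mk_h(grid[cells$a[i]], grid[cells$b[i]]))$ub_eff)
  single_of <- function(k, level) {
    h <- rep(0, d); h[k] <- level
    apply_inhibition(net, catalog, h)$ub_eff
  }
  ub_sa <- lapply(grid, function(g) single_of(ka, g))
  ub_sb <- lapply(grid, function(g) single_of(kb, g))
  bg_drugs <- which(bg > 0)
  ub_bg <- lapply(bg_drugs, function(k) single_of(k, bg[k]))
  sols <- if (norm == "L2")
    moma_l2_batch(net, v_ut, c(ub_cells, ub_sa, ub_sb, ub_bg))
  else moma_l1_batch(net, v_ut, c(ub_cells, ub_sa, ub_sb, ub_bg))
  vmod_of <- function(s) if (is.null(s)) NA_real_ else unname(s$v_tr[jmod])
  n_cells <- nrow(cells)
  vm_cells <- vapply(sols[seq_len(n_cells)], vmod_of, 0)
  vm_sa <- vapply(sols[n_cells + seq_len(ng)], vmod_of, 0)
  vm_sb <- vapply(sols[n_cells + ng + seq_len(ng)], vmod_of, 0)
  vm_bg <- vapply(sols[n_cells + 2L * ng + seq_along(bg_drugs)], vmod_of, 0)
  vut_mod <- v_ut[jmod]
  flux_pct <- matrix(NA_real_, ng, ng, dimnames = list(grid, grid))
  eta <- matrix(NA_real_, ng, ng, dimnames = list(grid, grid))
  for (i in seq_len(n_cells)) {
    ia <- cells$a[i]; ib <- cells$b[i]
    combined <- vm_cells[i]
    if (is.na(combined)) next
    flux_pct[ia, ib] <- 100 * combined / vut_mod
    singles <- c(vm_sa[ia], vm_sb[ib], vm_bg)
    if (!anyNA(singles))
      eta[ia, ib] <- nonlinearity_index(vut_mod, singles, combined)
  }
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 grid_a = grid, grid_b = grid,
                 background = stats::setNames(bg, catalog$drug_ids),
                 flux_pct = flux_pct, eta = eta,
                 mod_id = mod_id, norm_tag = norm, P = as.integer(P)),
            class = "interaction_surface")
}

#' @export
print.interaction_surface <- function(x, ...) {
  cat(sprintf("<interaction_surface %s x %s on %s (%s, P=%d): %dx%d grid>\n",
              x$drug_a, x$drug_b, x$mod_id, x$norm_tag, x$P,
              nrow(x$flux_pct), ncol(x$flux_pct)))
  invisible(x)
}

#' Screen all reactions for optimal drug combinations
#'
#' For every objective reaction and every threshold in `tau_list`, runs
#' [solve_bilevel()] (inhibit mode for `tau < 1`, activate mode for
#' `tau > 1`). Reactions with zero untreated flux are skipped with a
#' marker (a fractional threshold on a zero flux is vacuous). When the
#' same dosage vector `h` is found at several thresholds for the same
#' reaction, it is kept only at the most stringent one: the smallest
#' `tau` among inhibition thresholds, the largest among activation
#' thresholds. Per-cell failures are recorded, never abort the screen.
#'
#' @inheritParams solve_bilevel
#' @param tau_list Thresholds in `[0,1)` (inhibition) and/or `(1,Inf)`
#'   (activation).
#' @param mod_ids Reactions to screen (default: all reactions of the
#'   canonical network).
#' @param compute_eta Also evaluate the nonlinearity index of each
#'   solution (extra MOMA solves).
#' @return A `screening_result`: a data frame `records` (one row per
#'   (reaction, tau): status, h, cardinality, side effect, eta, kept)
#'   plus the run parameters; see [summary.screening_result()].
#' @export
screen_reactions <- function(net, v_ut, catalog, tau_list, P = 1,
                             scheme = c("binary", "dose"), b = 1e-3,
                             mod_ids = NULL, compute_eta = TRUE,
                             delta_max = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(net$canonical)
  v_ut_full <- v_ut
  v_ut <- ref_fluxes(v_ut)
  tau_list <- as.numeric(tau_list)
  if (length(tau_list) == 0L) stop("tau_list must be non-empty")
  if (any(tau_list < 0 | (tau_list >= 1 & tau_list <= 1)))
    stop("tau values must lie in [0,1) or (1,Inf)")
  mod_ids <- mod_ids %||% net$reaction_ids
  if (is.null(delta_max)) delta_max <- estimate_delta_max(net, v_ut, catalog)
  rec <- list()
  for (mod in mod_ids) {
    jmod <- match(mod, net$reaction_ids)
    for (tau in tau_list) {
      mode <- if (tau < 1) "inhibit" else "activate"
      if (v_ut[jmod] <= 1e-9) {
        rec[[length(rec) + 1L]] <- list(mod_id = mod, tau = tau, mode = mode,
                                        status = "skipped-zero-flux",
                                        solution = NULL)
        next
      }
      sol <- tryCatch(
        solve_bilevel(net, v_ut, catalog, mod, tau, mode, P, scheme, b,
                      delta_max = delta_max),
        error = function(e) e)
      if (inherits(sol, "error")) {
        status <- if (grepl("infeasible", conditionMessage(sol)))
          "infeasible" else "error"
        rec[[length(rec) + 1L]] <- list(mod_id = mod, tau = tau, mode = mode,
                                        status = status, solution = NULL,
                                        message = conditionMessage(sol))
      } else {
        rec[[length(rec) + 1L]] <- list(mod_id = mod, tau = tau, mode = mode,
                                        status = "optimal", solution = sol)
      }
    }
  }
  # most-stringent-threshold deduplication per (reaction, mode)
  kept <- rep(NA, length(rec))
  key <- vapply(rec, function(x) if (is.null(x$solution)) NA_character_
                else paste0(x$mod_id, "|", x$mode, "|",
                            paste(sprintf("%.9f", x$solution$h), collapse = ",")),
                "")
  for (i in seq_along(rec)) {
    if (is.na(key[i])) next
    grp <- which(key == key[i])
    taus <- vapply(rec[grp], `[[`, 0, "tau")
    best <- if (rec[[i]]$mode == "inhibit") grp[which.min(taus)]
    else grp[which.max(taus)]
    kept[i] <- i == best
  }
  if (compute_eta) {
    for (i in seq_along(rec)) {
      if (is.null(rec[[i]]$solution)) { rec[[i]]$eta <- NA_real_; next }
      jmod <- match(rec[[i]]$mod_id, net$reaction_ids)
      rec[[i]]$eta <- eta_for_h(net, v_ut, catalog, jmod,
                                rec[[i]]$solution$h,
                                extreme = if (rec[[i]]$mode == "activate")
                                  "max" else "min")
    }
  }
  records <- data.frame(
    mod_id = vapply(rec, `[[`, "", "mod_id"),
    tau = vapply(rec, `[[`, 0, "tau"),
    mode = vapply(rec, `[[`, "", "mode"),
    status = vapply(rec, `[[`, "", "status"),
    cardinality = vapply(rec, function(x) if (is.null(x$solution)) NA_integer_
                         else sum(x$solution$h > 1e-9), 0L),
    side_effect = vapply(rec, function(x) if (is.null(x$solution)) NA_real_
                         else x$solution$side_effect, 0),
    eta = if (compute_eta) vapply(rec, function(x) x$eta %||% NA_real_, 0)
    else NA_real_,
    kept = kept,
    stringsAsFactors = FALSE)
  structure(list(records = records,
                 solutions = lapply(rec, `[[`, "solution"),
                 P = as.integer(P), tau_list = tau_list, b = b),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: %d records (P=%d, tau in {%s})>\n",
              nrow(x$records), x$P, paste(x$tau_list, collapse = ", ")))
  print(table(x$records$status))
  invisible(x)
}

#' Summarize a screening run
#'
#' Produces the four standard summary tables of a reaction screening:
#' number of kept solutions per threshold, drug-cardinality frequencies,
#' side-effect values and nonlinearity-index values (the latter two pooled
#' over all thresholds).
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return List with `n_solutions`, `cardinality`, `side_effects`, `etas`.
#' @export
summary.screening_result <- function(object, ...) {
  rec <- object$records
  keep <- !is.na(rec$kept) & rec$kept & rec$status == "optimal"
  list(n_solutions = stats::aggregate(kept ~ tau, data = rec,
                                      FUN = function(k) sum(k, na.rm = TRUE)),
       cardinality = table(cardinality = rec$cardinality[keep]),
       side_effects = rec$side_effect[keep],
       etas = rec$eta[keep & !is.na(rec$eta)])
}
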