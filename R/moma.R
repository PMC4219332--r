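# Forward evaluation of treated fluxes: L1-MOMA (linear program, the inner
# problem of the bilevel formulation) and the quadratic L2-MOMA cross-check.

#' Side effect of a treatment
#'
#' The L1 distance `sum_i |v_tr_i - v_ut_i|` between treated and untreated
#' fluxes, summed over all reactions of the canonical network.
#'
#' @param v_tr,v_ut Flux vectors of equal length.
#' @return Non-negative flux sum.
#' @export
side_effect <- function(v_tr, v_ut) {
  if (length(v_tr) != length(v_ut))
    stop("flux vectors differ in length (", length(v_tr), " vs ",
         length(v_ut), ")")
  sum(abs(as.numeric(v_tr) - as.numeric(v_ut)))
}

as_bounded <- function(net, restricted_bounds = NULL) {
  if (inherits(net, "bounded_network")) return(net)
  if (is.null(restricted_bounds))
    return(list(network = net, ub_eff = net$upper_bounds))
  restricted_bounds
}

# LP for min sum(a) over {S v = 0, 0 <= v <= ub_eff, a >= |v - v_ut|}.
# Variables are (v_1..v_r, a_1..a_r).
moma_l1_problem <- function(net, v_ut, ub_eff) {
  r <- n_reactions(net)
  m <- n_metabolites(net)
  S <- net$stoich
  Zma <- matrix(0, m, r)
  I <- diag(r)
  A <- rbind(cbind(S, Zma),      # S v = 0
             cbind(I, -I),       # v - a <= v_ut
             cbind(-I, -I))      # -v - a <= -v_ut
  lp_problem(c(numeric(r), rep(1, r)), A,
             rlb = c(numeric(m), rep(-Inf, 2 * r)),
             rub = c(numeric(m), v_ut, -v_ut),
             lb = numeric(2 * r),
             ub = c(ub_eff, rep(Inf, r)))
}

moma_result <- function(net, v_ut, res, norm_tag) {
  r <- n_reactions(net)
  v <- stats::setNames(res$x[seq_len(r)], net$reaction_ids)
  structure(list(v_tr = v,
                 abs_devs = abs(v - v_ut),
                 side_effect = side_effect(v, v_ut),
                 norm_tag = norm_tag,
                 status = res$status),
            class = "treated_fluxes")
}

#' @export
print.treated_fluxes <- function(x, ...) {
  cat(sprintf("<treated_fluxes (%s): side effect %.6g over %d reactions>\n",
              x$norm_tag, x$side_effect, length(x$v_tr)))
  invisible(x)
}

#' L1-MOMA: minimal metabolic adjustment after treatment
#'
#' Computes `v_tr = argmin ||v - v_ut||_1` over the restricted flux
#' polytope `W(h)`. The absolute values are linearized through deviation
#' variables `a_i >= +/-(v_i - v_ut_i)`, giving a plain LP. Among
#' L1-equivalent optima the solver's vertex solution is returned; the
#' optimal value (the side effect) is unique even when `v_tr` is not.
#'
#' @param net Canonical [metabolic_network()].
#' @param v_ut Untreated fluxes: a [fba_reference()] result or a named
#'   numeric vector.
#' @param restricted_bounds A `bounded_network` from [apply_inhibition()];
#'   omit for the untreated bounds.
#' @return A `treated_fluxes` object: `v_tr`, `abs_devs`, `side_effect`,
#'   `norm_tag`, solver `status`.
#' @export
moma_l1 <- function(net, v_ut, restricted_bounds = NULL) {
  bw <- as_bounded(net, restricted_bounds)
  v_ut <- ref_fluxes(v_ut)
  res <- solve_program(moma_l1_problem(bw$network, v_ut, bw$ub_eff))
  if (res$status != "optimal")
    stop("L1-MOMA solve failed (status ", res$status, "): ", res$message)
  moma_result(bw$network, v_ut, res, "L1")
}

# Batched L1-MOMA over a list of effective-bound vectors (one python call).
moma_l1_batch <- function(net, v_ut, ub_list) {
  v_ut <- ref_fluxes(v_ut)
  probs <- lapply(ub_list, function(u) moma_l1_problem(net, v_ut, u))
  lapply(solve_programs(probs), function(res) {
    if (res$status != "optimal") return(NULL)
    moma_result(net, v_ut, res, "L1")
  })
}

#' L2-MOMA: quadratic minimal adjustment
#'
#' Same constraints as [moma_l1()] with the squared Euclidean distance
#' `||v - v_ut||_2^2` as objective. The strictly convex objective makes
#' the minimizer unique; used as a smoother cross-check of the L1
#' interaction surfaces. Solved by SLSQP; intended for small networks.
#'
#' @inheritParams moma_l1
#' @return A `treated_fluxes` object with `norm_tag = "L2"` (its
#'   `side_effect` is still reported as the L1 distance, the quantity the
#'   screening compares).
#' @export
moma_l2 <- function(net, v_ut, restricted_bounds = NULL) {
  bw <- as_bounded(net, restricted_bounds)
  v_ut <- ref_fluxes(v_ut)
  res <- solve_program(moma_l2_problem(bw$network, v_ut, bw$ub_eff))
  if (res$status != "optimal")
    stop("L2-MOMA solve failed: ", res$message)
  moma_result(bw$network, v_ut, res, "L2")
}

moma_l2_problem <- function(net, v_ut, ub_eff) {
  m <- n_metabolites(net)
  qp_problem(v_ut, net$stoich, rlb = numeric(m), rub = numeric(m),
             lb = numeric(n_reactions(net)), ub = ub_eff)
}

moma_l2_batch <- function(net, v_ut, ub_list) {
  v_ut <- ref_fluxes(v_ut)
  probs <- lapply(ub_list, function(u) moma_l2_problem(net, v_ut, u))
  lapply(solve_programs(probs), function(res) {
    if (res$status != "optimal") return(NULL)
    moma_result(net, v_ut, res, "L2")
  })
}

ref_fluxes <- function(v_ut) {
  if (is.list(v_ut) && !is.null(v_ut$v_ut)) v_ut$v_ut else as.numeric(v_ut)
}
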