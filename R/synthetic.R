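# Random toy networks and drug catalogs for tests and benchmarks.

#' Generate a random synthetic network and drug catalog
#'
#' The generator emulates small random test instances: a linear uptake ->
#' internal chain -> biomass backbone guarantees a connected network with a
#' strictly positive biomass optimum, and extra random internal conversions
#' (a fraction of them reversible) add branching and rerouting routes.
#' Drug target sets are drawn uniformly from the non-biomass reactions.
#' The instance is fully determined by `seed`.
#'
#' @param n_metabolites,n_reactions Network size; `n_reactions` must be at
#'   least `n_metabolites + 1` (backbone size).
#' @param n_drugs,targets_per_drug Catalog size.
#' @param seed Integer seed; same seed, same instance.
#' @param reversible_frac Probability that an extra reaction is reversible.
#' @param uptake_ub Upper bound of the uptake reaction (flux units).
#' @param ub_range Range from which internal upper bounds are drawn.
#' @param check Verify (via [fba_reference()]) that the biomass optimum is
#'   strictly positive; with the backbone construction this holds by design,
#'   the check guards against regressions.
#' @return List with elements `network` (original, possibly reversible form)
#'   and `catalog` (a [drug_catalog()]).
#' @export
generate_synthetic <- function(n_metabolites, n_reactions, n_drugs,
                               targets_per_drug, seed,
                               reversible_frac = 0.2, uptake_ub = 10,
                               ub_range = c(5, 20), check = TRUE) {
  stopifnot(n_metabolites >= 1, n_drugs >= 1, targets_per_drug >= 1)
  backbone <- n_metabolites + 1L
  if (n_reactions < backbone)
    stop("n_reactions must be >= n_metabolites + 1 (got ", n_reactions,
         " < ", backbone, "); increase n_reactions")
  with_seed(seed, {
    m <- n_metabolites
    mets <- paste0("M", seq_len(m))
    ids <- character(); cols <- list(); lb <- numeric(); ub <- numeric()
    rev <- logical()
    add <- function(id, coef, l, u, rv) {
      ids <<- c(ids, id)
      col <- stats::setNames(numeric(m), mets)
      col[names(coef)] <- coef
      cols[[id]] <<- col
      lb <<- c(lb, l); ub <<- c(ub, u); rev <<- c(rev, rv)
    }
    add("EX1", c(M1 = 1), 0, uptake_ub, FALSE)
    if (m >= 2)
      for (i in seq_len(m - 1L))
        add(paste0("R", i),
            stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
            0, stats::runif(1, ub_range[1], ub_range[2]), FALSE)
    add("BIO", stats::setNames(-1, mets[m]), 0,
        stats::runif(1, ub_range[1], ub_range[2]), FALSE)
    n_extra <- n_reactions - backbone
    for (e in seq_len(n_extra)) {
      pair <- sample.int(m, 2L)
      rv <- m >= 2 && stats::runif(1) < reversible_frac
      u <- stats::runif(1, ub_range[1], ub_range[2])
      if (m >= 2)
        add(paste0("X", e), stats::setNames(c(-1, 1), mets[pair]),
            if (rv) -stats::runif(1, ub_range[1], ub_range[2]) else 0, u, rv)
      else # single metabolite: an extra overflow sink
        add(paste0("X", e), c(M1 = -1), 0, u, FALSE)
    }
    S <- do.call(cbind, cols)
    net <- metabolic_network(S, lb, ub, rev, ids, mets, "BIO",
                             name = paste0("synthetic_seed", seed))
    targetable <- setdiff(ids, "BIO")
    if (targets_per_drug > length(targetable))
      stop("targets_per_drug exceeds number of targetable reactions")
    catalog <- drug_catalog(
      drug_ids = paste0("D", seq_len(n_drugs)),
      target_sets = lapply(seq_len(n_drugs), function(k)
        sample(targetable, targets_per_drug)))
    if (check) {
      ref <- fba_reference(make_irreversible(net))
      if (ref$objective_value <= 1e-6)
        stop("generated network has zero biomass optimum; ",
             "increase n_reactions or uptake_ub")
    }
    list(network = net, catalog = catalog)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
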