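# Shared in-code instances and independent oracles used across the suite.

# 2-reaction chain: uptake (U = 10) -> biomass.
make_chain <- function() {
  metabolic_network(matrix(c(1, -1), 1, 2,
                           dimnames = list("A", c("R_UP", "R_BIO"))),
                    lower_bounds = 0, upper_bounds = 10,
                    reversible = FALSE,
                    reaction_ids = c("R_UP", "R_BIO"),
                    metabolite_ids = "A", biomass_id = "R_BIO",
                    name = "chain")
}

chain_catalog <- function() drug_catalog("D1", list("R_UP"))

# 6-reaction branched net with one reversible shunt; used for independent
# vertex-enumeration checks.
make_branched <- function() {
  mets <- c("A", "B", "C")
  ids <- c("R_UP", "R_AB", "R_AC", "R_CB", "R_SH", "R_BIO")
  S <- matrix(0, 3, 6, dimnames = list(mets, ids))
  S["A", "R_UP"] <- 1
  S[c("A", "B"), "R_AB"] <- c(-1, 1)
  S[c("A", "C"), "R_AC"] <- c(-1, 1)
  S[c("C", "B"), "R_CB"] <- c(-1, 1)
  S[c("B", "C"), "R_SH"] <- c(-1, 1)   # reversible shunt B <-> C
  S["B", "R_BIO"] <- -1
  metabolic_network(S,
                    lower_bounds = c(0, 0, 0, 0, -4, 0),
                    upper_bounds = c(10, 6, 8, 8, 4, 20),
                    reversible = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                    reaction_ids = ids, metabolite_ids = mets,
                    biomass_id = "R_BIO", name = "branched")
}

canonical_ref <- function(net0) {
  net <- make_irreversible(net0)
  list(net = net, ref = fba_reference(net))
}

# Enumerate the vertices of {S v = 0, lb <= v <= ub} by fixing r - rank(S)
# coordinates at a bound and solving the remaining square system.
enumerate_vertices <- function(S, lb, ub, tol = 1e-9) {
  S <- as.matrix(S)
  r <- ncol(S)
  q <- qr(S)$rank
  nfix <- r - q
  verts <- list()
  for (fix in utils::combn(r, nfix, simplify = FALSE)) {
    free <- setdiff(seq_len(r), fix)
    Sf <- S[, free, drop = FALSE]
    if (qr(Sf)$rank < q) next
    for (pat in seq_len(2^nfix)) {
      bits <- as.integer(intToBits(pat - 1L))[seq_len(nfix)]
      vfix <- ifelse(bits == 1L, ub[fix], lb[fix])
      rhs <- -S[, fix, drop = FALSE] %*% vfix
      sol <- tryCatch(qr.solve(Sf, rhs, tol = 1e-12),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(r)
      v[fix] <- vfix
      v[free] <- sol
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1L]] <- v
    }
  }
  if (length(verts) == 0L) return(matrix(numeric(0), 0, r))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 7)), , drop = FALSE]
}

# Independent FBA value: maximum of a linear objective over the vertex set.
vertex_fba_value <- function(net, objective_id) {
  V <- enumerate_vertices(net$stoich, net$ref_lower, net$upper_bounds)
  j <- match(objective_id, net$reaction_ids)
  max(V[, j])
}
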