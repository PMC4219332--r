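# Drug catalogs, Boolean dosage encodings of the inhibition level h_k, and
# the application of inhibitions to flux upper bounds.

#' Construct a drug catalog
#'
#' @param drug_ids Unique drug identifier strings.
#' @param target_sets List (one element per drug) of reaction-id character
#'   vectors: the reactions whose enzymes the drug inhibits. Targets are
#'   given in the original network's ids; a drug targeting a reversible
#'   reaction constrains both halves of its irreversible split.
#' @param dose_levels Optional list (one element per drug, `NULL` allowed)
#'   of strictly increasing inhibition levels inside (0,1) measured in
#'   dose-response experiments; used by the `"dose"` encoding scheme.
#' @return An object of class `drug_catalog`.
#' @export
drug_catalog <- function(drug_ids, target_sets, dose_levels = NULL) {
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids")
  if (length(target_sets) != length(drug_ids))
    stop("target_sets must have one element per drug")
  target_sets <- lapply(target_sets, function(x) unique(as.character(x)))
  if (any(lengths(target_sets) == 0L)) stop("every drug needs >= 1 target")
  if (is.null(dose_levels)) dose_levels <- vector("list", length(drug_ids))
  if (length(dose_levels) != length(drug_ids))
    stop("dose_levels must have one element per drug (NULL allowed)")
  for (k in seq_along(dose_levels)) {
    lv <- dose_levels[[k]]
    if (is.null(lv)) next
    lv <- as.numeric(lv)
    if (any(lv <= 0 | lv >= 1) || is.unsorted(lv, strictly = TRUE))
      stop("dose levels of drug ", drug_ids[k],
           " must be strictly increasing and inside (0,1)")
    dose_levels[[k]] <- lv
  }
  structure(list(drug_ids = drug_ids,
                 target_sets = stats::setNames(target_sets, drug_ids),
                 dose_levels = stats::setNames(dose_levels, drug_ids)),
            class = "drug_catalog")
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat(sprintf("<drug_catalog: %d drugs, %d target assignments>\n",
              length(x$drug_ids), sum(lengths(x$target_sets))))
  invisible(x)
}

n_drugs <- function(catalog) length(catalog$drug_ids)

#' Validate a drug catalog against a network
#'
#' Checks that every target id exists in the network (original ids).
#' @param catalog A [drug_catalog()].
#' @param net A [metabolic_network()] in original form, or a canonical one
#'   (split ids are then also accepted).
#' @return `catalog`, invisibly.
#' @export
validate_catalog <- function(catalog, net) {
  known <- c(net$reaction_ids, names(net$split_map))
  for (k in seq_along(catalog$drug_ids)) {
    bad <- setdiff(catalog$target_sets[[k]], known)
    if (length(bad))
      stop("drug ", catalog$drug_ids[k], " targets unknown reaction(s): ",
           paste(bad, collapse = ", "))
  }
  invisible(catalog)
}

# Expand target sets to canonical reaction indices; a target that was split
# maps to both halves (enzyme inhibition acts on both directions).
resolve_targets <- function(catalog, net) {
  stopifnot(net$canonical)
  lapply(catalog$target_sets, function(ts) {
    ids <- unlist(lapply(ts, function(id) {
      pair <- net$split_map[[id]]
      if (is.null(pair)) id else unname(pair)
    }), use.names = FALSE)
    idx <- match(ids, net$reaction_ids)
    if (anyNA(idx))
      stop("target reaction absent from network: ",
           paste(ids[is.na(idx)], collapse = ", "))
    sort(unique(idx))
  })
}

# (drug, target) pair table on the canonical network; one row per dual
# variable delta.
target_pairs <- function(catalog, net) {
  tsets <- resolve_targets(catalog, net)
  data.frame(drug = rep.int(seq_along(tsets), lengths(tsets)),
             target = unlist(tsets, use.names = FALSE))
}

## --- catalog file format ----------------------------------------------------

#' Read or write a drug catalog file
#'
#' Line-oriented text format, one `drug:` record per drug:
#' `drug: <id> targets=<id1>,<id2>,... [levels=<l1>,<l2>,...]`
#'
#' @param path Catalog file.
#' @return A [drug_catalog()] (reader); `path` invisibly (writer).
#' @export
read_drug_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  ids <- character(); targets <- list(); levels <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^drug:\\s*(\\S+)\\s+(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("unparseable drug record: '", ln, "'")
    id <- kv[2L]
    fields <- strsplit(kv[3L], "[[:space:]]+")[[1L]]
    tg <- NULL; lv <- NULL
    for (f in fields) {
      p <- regmatches(f, regexec("^([a-z]+)=(.*)$", f))[[1L]]
      if (length(p) != 3L) stop("bad field '", f, "' in drug ", id)
      if (p[2L] == "targets") tg <- strsplit(p[3L], ",")[[1L]]
      else if (p[2L] == "levels") lv <- as.numeric(strsplit(p[3L], ",")[[1L]])
      else stop("unknown field '", p[2L], "' in drug ", id)
    }
    if (is.null(tg)) stop("drug ", id, " has no targets= field")
    ids <- c(ids, id)
    targets[[length(targets) + 1L]] <- tg
    levels[length(levels) + 1L] <- list(lv)   # keeps NULL entries
  }
  if (length(ids) == 0L) stop("catalog file contains no drugs")
  drug_catalog(ids, targets, levels)
}

#' @rdname read_drug_catalog
#' @param catalog A [drug_catalog()].
#' @export
write_drug_catalog <- function(catalog, path) {
  lines <- vapply(seq_along(catalog$drug_ids), function(k) {
    lv <- catalog$dose_levels[[k]]
    trimws(paste0("drug: ", catalog$drug_ids[k],
                  " targets=", paste(catalog$target_sets[[k]], collapse = ","),
                  if (!is.null(lv))
                    paste0(" levels=", paste(fmt_num(lv), collapse = ","))
                  else ""))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## --- dosage encodings -------------------------------------------------------

#' Dosage-encoding weights
#'
#' Weights `w` such that the inhibition level decodes as `h = sum(w * x)`
#' from the Boolean dosage vector `x`.
#'
#' For the binary-expansion scheme at precision `P` the weights are
#' `(1/2^P, 1/2, 1/4, ..., 1/2^P)` (the leading entry belongs to `x_0`,
#' which duplicates the smallest weight so that `h = 1` is reachable);
#' achievable values are exactly the grid `{m/2^P : m = 0..2^P}`.
#'
#' For the dose-response scheme with experimental levels
#' `0 < l_1 < ... < l_Q < 1` the weights are the increments
#' `(l_1, l_2 - l_1, ..., l_Q - l_{Q-1}, 1 - l_Q)` and valid Boolean
#' vectors are prefix-of-ones chains (`x_{j+1} <= x_j`), so the achievable
#' set is exactly `{0, l_1, ..., l_Q, 1}`.
#'
#' @param P Precision (binary scheme), integer `>= 0`.
#' @param levels Dose-response levels (dose scheme).
#' @return Numeric weight vector.
#' @export
encoding_weights_binary <- function(P) {
  P <- as.integer(P)
  if (P < 0) stop("precision P must be >= 0")
  c(1 / 2^P, if (P >= 1) 1 / 2^(1:P))
}

#' @rdname encoding_weights_binary
#' @export
encoding_weights_dose <- function(levels) {
  levels <- as.numeric(levels)
  if (length(levels) == 0L) stop("dose scheme needs at least one level")
  if (any(levels <= 0 | levels >= 1) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing and inside (0,1)")
  c(levels[1L], diff(levels), 1 - levels[length(levels)])
}

check_boolean <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(abs(x) > 1e-6 & abs(x - 1) > 1e-6))
    stop("dosage vector must be Boolean (0/1)")
  round(x)
}

#' Decode a binary-expansion dosage vector
#'
#' `h = x_0/2^P + sum_{n=1..P} x_n/2^n`, a value on the grid `{m/2^P}`.
#' Under the anti-redundancy convention, `x_0` may be 1 only when all other
#' entries are 1 (so `h = 1` has a unique encoding); [decode_binary()]
#' accepts any Boolean vector and does not enforce that convention.
#'
#' @param booleans Boolean vector of length `P + 1` (`x_0` first).
#' @param precision Integer `P >= 0`.
#' @return Inhibition fraction in `[0, 1]`.
#' @export
decode_binary <- function(booleans, precision) {
  precision <- as.integer(precision)
  x <- check_boolean(booleans)
  if (length(x) != precision + 1L)
    stop("dosage vector must have length P + 1 = ", precision + 1L)
  sum(encoding_weights_binary(precision) * x)
}

#' Decode a dose-response dosage vector
#'
#' Prefix-of-ones chains over the increment weights of
#' [encoding_weights_dose()]: a chain with the first `j` entries active
#' decodes to the `j`-th experimental level (all entries active decodes
#' to 1, none to 0).
#'
#' @param booleans Boolean vector of length `length(levels) + 1`.
#' @param levels Strictly increasing dose-response levels in (0,1).
#' @return Inhibition fraction: 0, one of `levels`, or 1.
#' @export
decode_dose_response <- function(booleans, levels) {
  w <- encoding_weights_dose(levels)
  x <- check_boolean(booleans)
  if (length(x) != length(w))
    stop("dosage vector must have length ", length(w))
  if (is.unsorted(rev(x)))
    stop("dosage vector must be a prefix-of-ones chain (x[j+1] <= x[j]); ",
         "violated at position ", which(diff(x) > 0)[1L] + 1L)
  sum(w * x)
}

# Per-drug encoding description used by the MILP and the oracle.
# scheme "binary": all drugs use binary expansion at precision P.
# scheme "dose": drugs with dose levels use the increment encoding, the
# others fall back to binary expansion at precision P.
drug_encodings <- function(catalog, P, scheme = c("binary", "dose")) {
  scheme <- match.arg(scheme)
  lapply(seq_len(n_drugs(catalog)), function(k) {
    lv <- catalog$dose_levels[[k]]
    if (scheme == "dose" && !is.null(lv))
      list(scheme = "dose", weights = encoding_weights_dose(lv),
           grid = c(0, lv, 1), levels = lv)
    else
      list(scheme = "binary", weights = encoding_weights_binary(P),
           grid = (0:2^P) / 2^P, P = as.integer(P))
  })
}

decode_h <- function(enc, x) sum(enc$weights * x)

## --- applying inhibition ----------------------------------------------------

#' Restrict flux bounds according to a drug treatment
#'
#' For every (drug `k`, target `i`) pair the constraint
#' `v_i <= U_i (1 - h_k)` is imposed; emitting one constraint per pair
#' makes the effective bound `U_i (1 - max_k h_k)`, i.e. the maximum
#' inhibition over the drugs hitting the enzyme (no allosteric
#' interaction is modelled).
#'
#' @param net Canonical [metabolic_network()].
#' @param catalog A [drug_catalog()].
#' @param h Numeric inhibition vector in `[0,1]^d` (one entry per drug).
#' @return A `bounded_network`: the network plus the restricted effective
#'   upper bounds (`ub_eff`) defining `W(h)`, the treatment `h` and the
#'   (drug, target) pair table.
#' @export
apply_inhibition <- function(net, catalog, h) {
  stopifnot(net$canonical)
  h <- as.numeric(h)
  if (length(h) != n_drugs(catalog))
    stop("h must have one entry per drug (", n_drugs(catalog), ")")
  if (any(is.na(h)) || any(h < -1e-12 | h > 1 + 1e-12))
    stop("inhibition levels h must lie in [0, 1]")
  h <- pmin(pmax(h, 0), 1)
  pairs <- target_pairs(catalog, net)
  ub_eff <- net$upper_bounds
  if (nrow(pairs)) {
    cap <- net$upper_bounds[pairs$target] * (1 - h[pairs$drug])
    for (p in seq_len(nrow(pairs)))
      ub_eff[pairs$target[p]] <- min(ub_eff[pairs$target[p]], cap[p])
  }
  structure(list(network = net, ub_eff = ub_eff,
                 h = stats::setNames(h, catalog$drug_ids), pairs = pairs),
            class = "bounded_network")
}
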