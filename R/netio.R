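# Metabolic network container, file formats, canonical (all-irreversible)
# form and the untreated reference flux state.

#' Construct a metabolic network
#'
#' A metabolic network is a stoichiometric matrix `S` (metabolites x
#' reactions) plus per-reaction flux bounds, reversibility flags and a
#' biomass (growth) reaction id. Flux units are arbitrary but must be
#' consistent across bounds.
#'
#' @param stoich Numeric matrix, metabolites in rows, reactions in columns.
#' @param lower_bounds,upper_bounds Per-reaction flux bounds, `L <= U`.
#' @param reversible Logical per-reaction reversibility flags.
#' @param reaction_ids,metabolite_ids Unique identifier strings; they must
#'   not contain whitespace or `:`.
#' @param biomass_id Id of the biomass reaction (the default FBA objective).
#' @param name Optional model name.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(stoich, lower_bounds, upper_bounds, reversible,
                              reaction_ids, metabolite_ids, biomass_id,
                              name = "model") {
  stoich <- as.matrix(stoich)
  r <- ncol(stoich)
  m <- nrow(stoich)
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(reaction_ids) != r) stop("reaction_ids length != ncol(stoich)")
  if (length(metabolite_ids) != m) stop("metabolite_ids length != nrow(stoich)")
  dup <- reaction_ids[duplicated(reaction_ids)]
  if (length(dup)) stop("duplicate reaction id: ", paste(unique(dup), collapse = ", "))
  dup <- metabolite_ids[duplicated(metabolite_ids)]
  if (length(dup)) stop("duplicate metabolite id: ", paste(unique(dup), collapse = ", "))
  bad <- grepl("[[:space:]:]", c(reaction_ids, metabolite_ids))
  if (any(bad)) stop("ids must not contain whitespace or ':'")
  lower_bounds <- rep_len(as.numeric(lower_bounds), r)
  upper_bounds <- rep_len(as.numeric(upper_bounds), r)
  reversible <- rep_len(as.logical(reversible), r)
  if (any(lower_bounds > upper_bounds))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reaction_ids[lower_bounds > upper_bounds], collapse = ", "))
  if (!is.null(biomass_id) && !biomass_id %in% reaction_ids)
    stop("biomass id not in network: ", biomass_id)
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  structure(list(stoich = stoich,
                 lower_bounds = stats::setNames(lower_bounds, reaction_ids),
                 upper_bounds = stats::setNames(upper_bounds, reaction_ids),
                 reversible = stats::setNames(reversible, reaction_ids),
                 reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids,
                 biomass_id = biomass_id,
                 split_map = list(),
                 ref_lower = stats::setNames(lower_bounds, reaction_ids),
                 canonical = !any(reversible) && all(lower_bounds >= 0),
                 name = name),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network '%s': %d metabolites x %d reactions%s>\n",
              x$name, length(x$metabolite_ids), length(x$reaction_ids),
              if (x$canonical) ", canonical (irreversible)" else ""))
  cat(sprintf("  biomass: %s; reversible: %d; split pairs: %d\n",
              x$biomass_id %||% "<none>", sum(x$reversible),
              length(x$split_map)))
  invisible(x)
}

n_reactions <- function(net) length(net$reaction_ids)
n_metabolites <- function(net) length(net$metabolite_ids)

## --- file formats -----------------------------------------------------------

#' Read a metabolic model from file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`structured`}{The package's line-oriented text format: `model:`,
#'     `biomass:`, `metabolite:` and `reaction:` records; see the schema at
#'     `system.file("extdata", "structured-model-schema.txt", package =
#'     "fluxmod")`.}
#'   \item{`tsv`}{A triplet table (columns `metabolite`, `reaction`,
#'     `coefficient`) plus a bounds table `<stem>.bounds.tsv` with columns
#'     `reaction`, `lb`, `ub`, `reversible`, `biomass`.}
#'   \item{`sbml`}{SBML Level 3 (fbc flux bounds honoured when present;
#'     otherwise defaults 0/1000, -1000/1000 for reversible reactions).}
#' }
#'
#' @param path Model file.
#' @param format One of `"structured"`, `"tsv"`, `"sbml"`.
#' @param biomass_id Optional override/supply of the biomass reaction id
#'   (required if the file does not name one).
#' @return A [metabolic_network()] in its original (possibly reversible) form.
#' @export
load_network <- function(path, format = c("structured", "tsv", "sbml"),
                         biomass_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  net <- switch(format,
                structured = read_structured_model(path),
                tsv = read_tsv_model(path),
                sbml = read_sbml_model(path))
  if (!is.null(biomass_id)) net$biomass_id <- biomass_id
  if (is.null(net$biomass_id))
    stop("model declares no biomass reaction; pass biomass_id=")
  if (!net$biomass_id %in% net$reaction_ids)
    stop("biomass id not in network: ", net$biomass_id)
  net
}

read_structured_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- "model"; biomass <- NULL
  mets <- character()
  rxn <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([a-z]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("unparseable record: '", ln, "'")
    key <- kv[2L]; rest <- trimws(kv[3L])
    if (key == "model") name <- rest
    else if (key == "biomass") biomass <- rest
    else if (key == "metabolite") mets <- c(mets, strsplit(rest, "[[:space:]]+")[[1L]])
    else if (key == "reaction") rxn[[length(rxn) + 1L]] <- parse_reaction_record(rest)
    else stop("unknown record type '", key, "' in: '", ln, "'")
  }
  if (length(rxn) == 0L) stop("model file contains no reactions")
  ids <- vapply(rxn, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate reaction id: ", paste(dup, collapse = ", "))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (rx in rxn) {
    unknown <- setdiff(names(rx$coef), mets)
    if (length(unknown))
      stop("reaction ", rx$id, " references undeclared metabolite: ",
           paste(unknown, collapse = ", "))
    S[names(rx$coef), rx$id] <- rx$coef
  }
  metabolic_network(S,
                    vapply(rxn, `[[`, 0, "lb"), vapply(rxn, `[[`, 0, "ub"),
                    vapply(rxn, `[[`, TRUE, "rev"),
                    ids, mets, biomass, name = name)
}

parse_reaction_record <- function(rest) {
  tok <- strsplit(rest, "[[:space:]]+")[[1L]]
  if (length(tok) < 4L)
    stop("bad reaction record (need 'id rev=.. lb=.. ub=..'): '", rest, "'")
  id <- tok[1L]
  fields <- tok[-1L]
  kv <- regmatches(fields, regexec("^([a-z]+)=(.*)$", fields))
  named <- vapply(kv, length, 0L) == 3L
  opts <- list()
  for (p in kv[named]) opts[[p[2L]]] <- p[3L]
  for (need in c("rev", "lb", "ub"))
    if (is.null(opts[[need]])) stop("reaction ", id, " missing field ", need)
  pairs <- fields[!named]
  coef <- numeric(0)
  for (p in pairs) {
    sp <- regmatches(p, regexec("^(.*):([^:]+)$", p))[[1L]]
    if (length(sp) != 3L) stop("bad metabolite:coefficient pair '", p,
                               "' in reaction ", id)
    v <- suppressWarnings(as.numeric(sp[3L]))
    if (is.na(v)) stop("non-numeric coefficient in '", p, "' (reaction ", id, ")")
    coef[sp[2L]] <- v
  }
  list(id = id, rev = as.numeric(opts$rev) != 0,
       lb = as.numeric(opts$lb), ub = as.numeric(opts$ub), coef = coef)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) formatC(v, format = "g", digits = 15), "")
  trimws(out)
}

#' Write a metabolic model to file
#'
#' Writers emit byte-stable output for a fixed input ordering, so a
#' write/read round trip is the identity on stoichiometry, bounds and ids.
#'
#' @param net A [metabolic_network()].
#' @param path Output file (for `tsv`, the bounds table is written next to
#'   it as `<stem>.bounds.tsv`).
#' @param format `"structured"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("structured", "tsv")) {
  format <- match.arg(format)
  if (format == "structured") {
    lines <- c(paste0("model: ", net$name),
               paste0("biomass: ", net$biomass_id),
               paste0("metabolite: ", net$metabolite_ids))
    for (j in seq_along(net$reaction_ids)) {
      id <- net$reaction_ids[j]
      col <- net$stoich[, j]
      nz <- which(col != 0)
      pairs <- if (length(nz))
        paste0(net$metabolite_ids[nz], ":", fmt_num(col[nz]), collapse = " ")
      else ""
      lines <- c(lines, trimws(sprintf("reaction: %s rev=%d lb=%s ub=%s %s",
                                       id, as.integer(net$reversible[j]),
                                       fmt_num(net$lower_bounds[j]),
                                       fmt_num(net$upper_bounds[j]), pairs)))
    }
    writeLines(lines, path)
  } else {
    nz <- which(net$stoich != 0, arr.ind = TRUE)
    ord <- order(nz[, 2L], nz[, 1L])
    nz <- nz[ord, , drop = FALSE]
    trip <- data.frame(metabolite = net$metabolite_ids[nz[, 1L]],
                       reaction = net$reaction_ids[nz[, 2L]],
                       coefficient = fmt_num(net$stoich[nz]))
    utils::write.table(trip, path, sep = "\t", quote = FALSE, row.names = FALSE)
    bounds <- data.frame(reaction = net$reaction_ids,
                         lb = fmt_num(net$lower_bounds),
                         ub = fmt_num(net$upper_bounds),
                         reversible = as.integer(net$reversible),
                         biomass = as.integer(net$reaction_ids == net$biomass_id))
    utils::write.table(bounds, tsv_bounds_path(path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

tsv_bounds_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".bounds.tsv")
}

read_tsv_model <- function(path) {
  trip <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "reaction", "coefficient")
  if (!all(need %in% names(trip)))
    stop("triplet table must have columns: ", paste(need, collapse = ", "))
  bpath <- tsv_bounds_path(path)
  if (!file.exists(bpath)) stop("bounds table not found: ", bpath)
  bounds <- utils::read.delim(bpath, stringsAsFactors = FALSE)
  ids <- bounds$reaction
  mets <- unique(trip$metabolite)
  unknown <- setdiff(trip$reaction, ids)
  if (length(unknown))
    stop("triplet table references reaction absent from bounds table: ",
         paste(unknown, collapse = ", "))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  S[cbind(match(trip$metabolite, mets), match(trip$reaction, ids))] <-
    as.numeric(trip$coefficient)
  biomass <- ids[as.logical(bounds$biomass)]
  metabolic_network(S, as.numeric(bounds$lb), as.numeric(bounds$ub),
                    as.logical(bounds$reversible), ids, mets,
                    if (length(biomass)) biomass[1L] else NULL,
                    name = tools::file_path_sans_ext(basename(path)))
}

read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("SBML file contains no reactions")
  ids <- xml2::xml_attr(rx, "id")
  rev <- xml2::xml_attr(rx, "reversible") %in% c("true", "1")
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  lb <- ifelse(rev, -1000, 0)
  ub <- rep(1000, length(ids))
  for (j in seq_along(rx)) {
    for (ref in xml2::xml_find_all(rx[[j]], "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      S[sp, j] <- S[sp, j] - ifelse(is.na(st), 1, as.numeric(st))
    }
    for (ref in xml2::xml_find_all(rx[[j]], "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      S[sp, j] <- S[sp, j] + ifelse(is.na(st), 1, as.numeric(st))
    }
    lbid <- xml2::xml_attr(rx[[j]], "lowerFluxBound")
    ubid <- xml2::xml_attr(rx[[j]], "upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(pval)) lb[j] <- pval[[lbid]]
    if (!is.na(ubid) && ubid %in% names(pval)) ub[j] <- pval[[ubid]]
  }
  # boundary species do not constrain the steady state
  if (any(boundary)) {
    S <- S[!boundary, , drop = FALSE]
    mets <- mets[!boundary]
  }
  obj <- xml2::xml_find_first(doc, ".//listOfFluxObjectives/fluxObjective")
  biomass <- if (!inherits(obj, "xml_missing")) xml2::xml_attr(obj, "reaction")
  else {
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1L] else NULL
  }
  metabolic_network(S, lb, ub, rev, ids, mets, biomass,
                    name = tools::file_path_sans_ext(basename(path)))
}

## --- canonical irreversible form -------------------------------------------

#' Decompose reversible reactions into irreversible pairs
#'
#' Every reversible reaction `j` with `L_j < 0` is replaced by a forward
#' copy (`[0, U_j]`, original column) and a backward copy (`[0, -L_j]`,
#' negated column), so that all fluxes in the canonical network are
#' non-negative. Reactions flagged reversible but with `L_j >= 0` are
#' treated as irreversible with a warning. Positive lower bounds are
#' relaxed to 0 in the canonical form (the bilevel machinery assumes
#' `L_i = 0`); the original values are kept in `ref_lower` and enforced
#' only in the reference-FBA stage.
#'
#' @param net A [metabolic_network()].
#' @return A canonical `metabolic_network` with `split_map` recording each
#'   original id and its forward/backward pair.
#' @export
make_irreversible <- function(net) {
  if (net$canonical && all(net$lower_bounds == 0)) return(net)
  to_split <- net$reversible & net$lower_bounds < 0
  odd <- net$reversible & net$lower_bounds >= 0
  if (any(odd))
    warning("reaction(s) flagged reversible with non-negative lower bound ",
            "treated as irreversible: ",
            paste(net$reaction_ids[odd], collapse = ", "))
  cols <- list(); ids <- character(); ub <- numeric(); ref_lb <- numeric()
  split_map <- list()
  for (j in seq_along(net$reaction_ids)) {
    id <- net$reaction_ids[j]
    if (to_split[j]) {
      fwd <- paste0(id, "_f"); bwd <- paste0(id, "_b")
      if (any(c(fwd, bwd) %in% net$reaction_ids))
        stop("split would collide with existing reaction id: ", fwd, "/", bwd)
      cols[[fwd]] <- net$stoich[, j]
      cols[[bwd]] <- -net$stoich[, j]
      ids <- c(ids, fwd, bwd)
      ub <- c(ub, net$upper_bounds[j], -net$lower_bounds[j])
      ref_lb <- c(ref_lb, 0, 0)
      split_map[[id]] <- c(forward = fwd, backward = bwd)
    } else {
      cols[[id]] <- net$stoich[, j]
      ids <- c(ids, id)
      ub <- c(ub, net$upper_bounds[j])
      ref_lb <- c(ref_lb, max(0, net$lower_bounds[j]))
    }
  }
  S <- do.call(cbind, cols)
  biomass <- net$biomass_id
  if (!is.null(biomass) && !is.null(split_map[[biomass]]))
    biomass <- split_map[[biomass]][["forward"]]
  out <- metabolic_network(S, 0, ub, FALSE, ids, net$metabolite_ids,
                           biomass, name = net$name)
  out$split_map <- split_map
  out$ref_lower <- stats::setNames(ref_lb, ids)
  out$canonical <- TRUE
  out
}

# Map a (possibly signed) flux vector on the original network onto the
# canonical split coordinates.
split_fluxes <- function(net_canon, net_orig, v) {
  out <- stats::setNames(numeric(n_reactions(net_canon)),
                         net_canon$reaction_ids)
  for (id in net_orig$reaction_ids) {
    pair <- net_canon$split_map[[id]]
    if (is.null(pair)) out[id] <- v[[id]]
    else {
      out[pair[["forward"]]] <- max(v[[id]], 0)
      out[pair[["backward"]]] <- max(-v[[id]], 0)
    }
  }
  out
}

## --- reference (untreated) fluxes ------------------------------------------

#' Compute the untreated reference flux state
#'
#' Two-stage LP on the canonical network: (i) maximize the objective
#' (biomass) flux subject to the steady-state and bound constraints;
#' (ii) with the objective fixed at its optimum, minimize the total flux
#' `sum_i v_i`. The second, lexicographic stage is the determinization
#' rule that removes dependence on degenerate FBA optima; its label is
#' recorded in `tie_break_tag`.
#'
#' @param net Canonical [metabolic_network()] (see [make_irreversible()]).
#' @param objective_id Reaction to maximize; default the biomass id.
#' @param tol Feasibility tolerance (default `1e-9`), reported in the result.
#' @return List with `v_ut` (named flux vector), `objective_value`,
#'   `tie_break_tag` and `tol`.
#' @export
fba_reference <- function(net, objective_id = NULL, tol = 1e-9) {
  if (!net$canonical) stop("fba_reference requires a canonical network; ",
                           "call make_irreversible() first")
  objective_id <- objective_id %||% net$biomass_id
  jobj <- match(objective_id, net$reaction_ids)
  if (is.na(jobj)) stop("objective reaction not in network: ", objective_id)
  probs <- fba_reference_problems(net, jobj)
  res1 <- solve_program(probs$stage1)
  if (res1$status != "optimal")
    stop("reference FBA failed (", res1$status, "): ", res1$message)
  opt <- -res1$objective
  res2 <- solve_program(fba_stage2_problem(net, jobj, opt, tol))
  if (res2$status != "optimal")
    stop("reference FBA tie-break stage failed (", res2$status, "): ",
         res2$message)
  v <- stats::setNames(res2$x, net$reaction_ids)
  list(v_ut = v, objective_value = opt,
       tie_break_tag = "max-objective+lexmin-total-flux", tol = tol)
}

fba_reference_problems <- function(net, jobj) {
  r <- n_reactions(net)
  obj <- numeric(r); obj[jobj] <- -1
  list(stage1 = lp_problem(obj, net$stoich,
                           rlb = numeric(n_metabolites(net)),
                           rub = numeric(n_metabolites(net)),
                           lb = net$ref_lower, ub = net$upper_bounds))
}

fba_stage2_problem <- function(net, jobj, opt, tol) {
  r <- n_reactions(net)
  fix <- numeric(r); fix[jobj] <- 1
  A <- rbind(net$stoich, fix)
  # fixing the objective exactly is safe: the solver's own feasibility
  # tolerance absorbs the stage-1 rounding
  lp_problem(rep(1, r), A,
             rlb = c(numeric(n_metabolites(net)), opt),
             rub = c(numeric(n_metabolites(net)), opt),
             lb = net$ref_lower, ub = net$upper_bounds)
}
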