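# Curated, hand-checkable worked-example instances. The model/drug files
# double as documentation of the structured text formats; the expected
# values are certified against the exhaustive oracle by the test suite.

fixture_registry <- list(
  chain = list(
    mod_id = "R_BIO", tau = 0.5, mode = "inhibit", P = 1L,
    expected = list(
      v_ut = c(R_UP = 10, R_BIO = 10),
      h = c(D1 = 0.5), side_effect = 10,
      p0_h = c(D1 = 1), p0_side_effect = 20),
    provenance = paste("2-reaction chain, hand LP: tau=0.5 forces the",
                       "biomass flux to 5; at P=1 the half dose h=0.5 does",
                       "exactly that (side effect 10), at P=0 only the full",
                       "stop h=1 qualifies (side effect 20).")),
  diamond = list(
    mod_id = "R_BIO", tau = 0.5, mode = "inhibit", P = 1L,
    expected = list(
      v_ut = c(R_UP = 10, R_C = 10, R_A = 10, R_M1 = 0, R_M2 = 0,
               R_BIO = 10),
      moma_h1_side_effect = 30,
      moma_h1_v_tr = c(R_UP = 10, R_C = 10, R_A = 0, R_M1 = 10, R_M2 = 10,
                       R_BIO = 10),
      infeasible = TRUE),
    provenance = paste("Blocking the direct route reroutes all flux through",
                       "the 2-step bypass (cost 30 < shutdown 40); biomass",
                       "never drops, so inhibiting it is infeasible.")),
  `superfluous-drug` = list(
    mod_id = "R_BIO", tau = 0.25, mode = "inhibit", P = 2L,
    expected = list(
      v_ut = c(R_IN1 = 10, R_IN2 = 10, R_BIO = 20),
      h = c(DK = 0, DL = 0.75), side_effect = 30),
    provenance = paste("DK's targets are a subset of DL's; capping biomass",
                       "at 5 needs both uptakes at 2.5 (h=0.75 via DL);",
                       "the b-term forces h_DK = 0.")),
  activation = list(
    mod_id = "R_M2", tau = 1.5, mode = "activate", P = 2L,
    expected = list(
      v_ut = c(R_UP = 10, R_A = 6, R_M1 = 4, R_M2 = 4, R_BIO = 10),
      h = c(D1 = 0.5), side_effect = 9),
    provenance = paste("Inhibiting the saturated direct route pushes flux",
                       "onto the bypass; h=0.5 allows an inner optimum with",
                       "bypass flux 7 >= 1.5*4, side effect 18h = 9."))
)

fixture_file <- function(stem, ext) {
  f <- system.file("extdata", "fixtures", paste0(stem, ".", ext),
                   package = "fluxmod")
  if (!nzchar(f)) stop("fixture data file missing: ", stem, ".", ext)
  f
}

#' Registered worked-example fixtures
#'
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() names(fixture_registry)

#' Load a worked-example fixture
#'
#' Tiny hand-checkable instances used across tests and documentation:
#' `"chain"` (the partial-inhibition showcase), `"diamond"` (flux
#' rerouting; infeasible inhibition), `"superfluous-drug"` (dominated
#' drug dropped by the anti-overselection term) and `"activation"`
#' (up-regulation with `tau > 1`). The `expected` values are certified
#' against [exhaustive_oracle()] by the test suite on every run.
#'
#' @param name Fixture name; see [fixture_names()].
#' @return List with `name`, `network` (original form), `catalog`,
#'   `mod_id`, `tau`, `mode`, `P`, `expected` and a `provenance` note.
#' @export
fixture <- function(name) {
  spec <- fixture_registry[[name]]
  if (is.null(spec))
    stop("unknown fixture '", name, "'; registered: ",
         paste(fixture_names(), collapse = ", "))
  stem <- sub("-drug$", "", name)
  net <- load_network(fixture_file(stem, "model"), format = "structured")
  catalog <- read_drug_catalog(fixture_file(stem, "drugs"))
  c(list(name = name, network = net, catalog = catalog), spec)
}
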