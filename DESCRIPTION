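Package: fluxmod
Title: Minimal-Side-Effect Drug Combinations on Metabolic Networks via
    Bilevel Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("fluxmod", "developers", email = "fluxmod@example.org",
           role = c("aut", "cre"))
Description: Constraint-based search for multi-drug treatments that modulate
    a target reaction flux with minimal perturbation of the rest of the
    metabolic network. Partial enzyme inhibition is encoded as a convex
    combination of Boolean dosage variables, and the nested
    flux-balance/L1-MOMA problem is folded into a single mixed-integer
    linear program via LP strong duality with big-M linearization.
    Includes forward MOMA evaluation (L1 and L2), an exhaustive-search
    oracle, drug-interaction surfaces, a nonlinearity (synergy) index,
    an all-reactions screening protocol, synthetic network generation,
    and command-line drivers. Optimization is delegated to the HiGHS
    solver through SciPy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy on the PATH
Config/testthat/edition: 3
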