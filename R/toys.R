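# Small bundled networks with exhaustively enumerable isotopomer spaces.
# They exercise every structural feature of the EMU machinery (linear
# chains, condensations, cleavage, branch points, symmetric scrambling,
# cycles) and serve as the cross-check surface against brute-force
# isotopomer simulation.

TOY_CONFIGS <- list(
  # linear chain: label passes through unchanged
  chain = c(
    "input: A.e",
    "up: A.e -> B.c | ab -> ab | irr",
    "r1: B.c -> C.c | ab -> ab | irr",
    "out: C.c -> D.e | ab -> ab | irr"),
  # condensation of two one-carbon inputs (one convolution transition)
  condense = c(
    "input: A.e B.e",
    "upA: A.e -> X.c | a -> a | irr",
    "upB: B.e -> Y.c | a -> a | irr",
    "r1: X.c + Y.c -> C.c | a + b -> ab | irr",
    "out: C.c -> D.e | ab -> ab | irr"),
  # branch point: one route keeps all three carbons, the other loses C3 to
  # CO2 and regains an unlabeled carbon; the branch ratio is identifiable
  # from the product MDV
  branch = c(
    "input: A.e C1.e",
    "up: A.e -> S.c | abc -> abc | irr",
    "r1: S.c -> P.c | abc -> abc | irr",
    "r2: S.c -> D.c + CO2.c | abc -> ab + c | irr",
    "r3: D.c + E.c -> P.c | ab + d -> abd | irr",
    "upC: C1.e -> E.c | a -> a | irr",
    "co2: CO2.c -> CO2.e | a -> a | irr",
    "out: P.c -> P.e | abc -> abc | irr"),
  # symmetric intermediate: positional scrambling visible on a sub-fragment
  symmetry = c(
    "input: A.e",
    "symmetric: S.c",
    "up: A.e -> S.c | abcd -> abcd | irr",
    "r1: S.c -> M.c | abcd -> abcd | irr",
    "out: M.c -> M.e | abcd -> abcd | irr"),
  # condensation-cleavage cycle with a symmetric intermediate and an
  # anaplerotic inflow (a miniature TCA cycle)
  cycle = c(
    "input: AC.e IN.e",
    "symmetric: S4.c",
    "upA: AC.e -> ACX.c | ab -> ab | irr",
    "upI: IN.e -> O.c | abcd -> abcd | irr",
    "r1: ACX.c + O.c -> C6.c | ab + cdef -> fedbac | irr",
    "r2: C6.c -> K5.c + CO2.c | abcdef -> abcde + f | irr",
    "r3: K5.c -> S4.c + CO2.c | abcde -> bcde + a | irr",
    "r4: S4.c -> O.c | abcd -> abcd | irr",
    "r5: O.c -> O.e | abcd -> abcd | irr",
    "co2: CO2.c -> CO2.e | a -> a | irr"))

TOY_FRAGMENTS <- list(
  chain = list(list(id = "C", parts = list(list(met = "C.c", atoms = 1:2)))),
  condense = list(list(id = "C", parts = list(list(met = "C.c", atoms = 1:2)))),
  branch = list(list(id = "P", parts = list(list(met = "P.c", atoms = 1:3)))),
  symmetry = list(
    list(id = "Mfull", parts = list(list(met = "M.c", atoms = 1:4))),
    list(id = "Mhead", parts = list(list(met = "M.c", atoms = 1:2)))),
  cycle = list(
    list(id = "O", parts = list(list(met = "O.c", atoms = 1:4))),
    list(id = "K5", parts = list(list(met = "K5.c", atoms = 1:5))),
    list(id = "Ohead", parts = list(list(met = "O.c", atoms = 1:2)))))

#' Bundled toy networks
#'
#' Small networks (a linear chain, a two-input condensation, a carbon-loss
#' branch point, a symmetric intermediate, and a condensation-cleavage
#' cycle) whose isotopomer spaces are small enough for exhaustive
#' enumeration; used to validate the EMU simulator against a brute-force
#' oracle and to calibrate the goodness-of-fit machinery cheaply.
#'
#' @param name One of `"chain"`, `"condense"`, `"branch"`, `"symmetry"`,
#'   `"cycle"`.
#' @return A `flux_network` with its measurement fragments attached.
#' @export
toy_network <- function(name = c("chain", "condense", "branch", "symmetry",
                                 "cycle")) {
  name <- match.arg(name)
  net <- read_network_config(text = TOY_CONFIGS[[name]])
  net$fragments <- TOY_FRAGMENTS[[name]]
  net$mode <- paste0("toy:", name)
  net
}

#' Names of the bundled toy networks
#' @return Character vector.
#' @export
toy_network_names <- function() names(TOY_CONFIGS)

#' A simple labeled-input tracer for the toy networks
#'
#' Labels position 1 of every input metabolite at the given fraction and
#' purity; remaining positions (and the unlabeled complement species) are at
#' natural abundance.
#'
#' @param network A toy `flux_network`.
#' @param fraction Labeled fraction per input pool.
#' @param purity Isotopic purity of the labeled position.
#' @param natural_abundance Natural 13C abundance (set 0 for crisp
#'   analytical cases).
#' @param positions Which positions to label (default 1).
#' @return A `tracer_mixture`.
#' @export
toy_tracer <- function(network, fraction = 0.5, purity = 1,
                       natural_abundance = 0, positions = 1) {
  sp <- do.call(rbind, lapply(network$inputs, function(s) {
    if (fraction < 1)
      rbind(new_species(s, positions, fraction, purity),
            new_species(s, integer(0), 1 - fraction, purity))
    else new_species(s, positions, 1, purity)
  }))
  tracer_mixture(sp, natural_abundance)
}
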