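# Bundled compartmentalized Y. lipolytica central-metabolism models.

#' Measured GC-MS fragment panel
#'
#' The carbon backbones of proteinogenic amino acids routinely quantified in
#' GC-MS flux studies, expressed through their biosynthetic precursor pools,
#' plus secreted citrate.  A fragment is a convolution of one or more
#' precursor EMUs; the mass distribution of a full carbon backbone depends
#' only on which precursor atoms contribute, so amino acids are handled as
#' measurement-only pools without back-flux into the network.
#'
#' @return A list of fragment specifications, each a list with `id` and
#'   `parts` (list of `list(met, atoms)`).
#' @export
yarrowia_fragments <- function() {
  frag <- function(id, ...) list(id = id, parts = list(...))
  part <- function(met, atoms) list(met = met, atoms = as.integer(atoms))
  list(
    frag("Ala", part("PYR.c", 1:3)),
    frag("Gly", part("PGA.c", 1:2)),
    frag("Ser", part("PGA.c", 1:3)),
    frag("Val", part("PYR.m", 1:3), part("PYR.m", 2:3)),
    frag("Thr", part("OAA.c", 1:4)),
    frag("Asp", part("OAA.c", 1:4)),
    frag("Glu", part("AKG.m", 1:5)),
    frag("Phe", part("PEP.c", 1:3), part("PEP.c", 2:3), part("E4P.c", 1:4)),
    frag("Cit", part("CIT.c", 1:6))
  )
}

#' Build the bundled Y. lipolytica central-metabolism network
#'
#' Loads the compartmentalized network (glycolysis, oxidative and
#' non-oxidative pentose phosphate pathway, TCA cycle, pyruvate carboxylase,
#' the citrate-malate shuttle with ATP:citrate lyase as the only cytosolic
#' acetyl-CoA source, lipid and biomass drains, and a tracked CO2 pool) for
#' the requested substrate mode, and attaches the measured fragment panel.
#'
#' Glycerol enters via glycerol 3-phosphate and the membrane-bound
#' glycerol-3-phosphate dehydrogenase step to DHAP (modes `"glycerol"` and
#' `"dual"`).  The PFK step is modeled as a single reversible
#' phosphofructokinase/fructose-bisphosphatase pair so the hexose pool can
#' be replenished gluconeogenically on glycerol.
#'
#' @param substrate_mode One of `"glucose"`, `"glycerol"`, `"dual"`.
#' @return A `flux_network` with `fragments`, `mode`, and the expected
#'   null-space dimension (`nfree_declared`) attached.
#' @examples
#' net <- build_yarrowia_network("glucose")
#' validate_carbon_balance(net)   # character(0)
#' @export
build_yarrowia_network <- function(substrate_mode = c("glucose", "glycerol", "dual")) {
  substrate_mode <- match.arg(substrate_mode)
  path <- system.file("extdata", paste0("yl_", substrate_mode, ".txt"),
                      package = "fluxome", mustWork = TRUE)
  net <- read_network_config(path)
  net$fragments <- yarrowia_fragments()
  net$mode <- substrate_mode
  net$nfree_declared <- switch(substrate_mode, glucose = 5L, glycerol = 5L, dual = 6L)
  net
}
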