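# Seeded synthetic-data generators: ground-truth flux maps, noisy GC-MS
# measurement tables, fermentation time courses and two-phase expression
# tables.  Fixed seed implies byte-identical output.

#' Sample a random feasible steady-state flux map
#'
#' Draws the free net fluxes uniformly within their boxes, completes the
#' map through the affine steady-state parameterization (uptake pinned to
#' 100), and rejects draws for which any irreversible reaction would run
#' backwards.  Exchange fluxes of reversible reactions are drawn uniformly
#' on `exch_range`.
#'
#' @param network A `flux_network`.
#' @param seed Integer seed (same seed, same map).
#' @param bounds Box for irreversible free net fluxes.
#' @param exch_range Range for exchange-flux draws.
#' @param fixed Named numeric vector pinning a subset of the free fluxes
#'   (e.g. `c(g6pdh = 35)`).
#' @param max_draws Rejection budget (error when exhausted).
#' @param param Optional precomputed [flux_parameterization()].
#' @return A feasible `flux_map` normalized to uptake = 100.
#' @export
random_feasible_fluxmap <- function(network, seed = 1, bounds = c(0, 150),
                                    exch_range = c(0, 10), fixed = NULL,
                                    max_draws = 1e4, param = NULL) {
  if (is.null(param)) param <- flux_parameterization(network)
  if (!is.null(fixed) && !all(names(fixed) %in% param$free))
    stop("fixed fluxes must be free fluxes (", paste(param$free, collapse = ", "), ")")
  rng <- local({ set.seed(seed); function(n, lo, hi) stats::runif(n, lo, hi) })
  free_rev <- param$free %in% param$reversible
  lo <- ifelse(free_rev, -bounds[2], bounds[1])
  hi <- rep(bounds[2], param$nfree)
  for (k in seq_len(max_draws)) {
    vfree <- rng(param$nfree, lo, hi)
    names(vfree) <- param$free
    if (!is.null(fixed)) vfree[names(fixed)] <- fixed
    net <- drop(param$d + param$C %*% vfree)
    names(net) <- param$ids
    if (all(net[param$irreversible] >= 0) && all(abs(net) <= 3 * bounds[2])) {
      ex <- stats::setNames(rng(length(param$reversible), exch_range[1], exch_range[2]),
                            param$reversible)
      return(flux_map(net, ex, basis = param$uptakes))
    }
  }
  stop("rejection budget exhausted (", max_draws,
       " draws) without a feasible flux map")
}

#' Simulate a noisy GC-MS measurement table
#'
#' Simulates the fragment panel MDVs for a flux map and tracer mixture,
#' adds independent Gaussian noise of standard deviation `sd` to every mass
#' fraction, renormalizes each fragment MDV to sum 1, and attaches `sd`.
#'
#' @param emu_net An `emu_network`.
#' @param flux A `flux_map`.
#' @param mixture A `tracer_mixture`.
#' @param sd Noise standard deviation in mol fraction (0 = exact).
#' @param seed Integer seed.
#' @return An [mdv_measurements()] table.
#' @export
synthetic_mdv_measurements <- function(emu_net, flux, mixture, sd = 0.004,
                                       seed = 1) {
  sim <- simulate_mdvs(emu_net, flux, mixture)
  set.seed(seed)
  frag <- character(0); mass <- integer(0); value <- numeric(0)
  for (id in names(sim)) {
    m <- sim[[id]]
    if (sd > 0) {
      m <- m + stats::rnorm(length(m), 0, sd)
      m <- m / sum(m)
    }
    frag <- c(frag, rep(id, length(m)))
    mass <- c(mass, seq_along(m) - 1L)
    value <- c(value, m)
  }
  # noise-free tables keep the default GC-MS repeatability as the weighting sd
  mdv_measurements(frag, mass, value, sd = if (sd > 0) sd else 0.004)
}

#' Default synthetic-generator configuration
#'
#' The fermentation defaults mirror the pO2-controlled dual-substrate
#' (glucose + glycerol) bioreactor scenario: maximum specific growth rate
#' 0.22 1/h, glycerol consumed at 0.70 g/L/h and glucose at 0.30 g/L/h from
#' 45 g/L each, nitrogen limitation at 15 h, citrate produced at 0.6 g/L/h
#' after the nitrogen-limitation onset.  Expression defaults mirror the
#' pO2-controlled two-phase comparison: 3000 genes with 640 up- and 290
#' down-regulated at planted |log2 fold changes| >= 1.5, two replicates per
#' phase, 4e6 mapped fragments per sample.
#'
#' @param seed Integer seed.
#' @return Nested list of generator settings.
#' @export
generator_config <- function(seed = 1) {
  list(
    seed = seed,
    fermentation = list(
      mu = 0.22, rates = c(glycerol = 0.70, glucose = 0.30),
      initial = c(biomass = 0.2, glycerol = 45, glucose = 45, citrate = 0,
                  ammonium = 0.5),
      n_onset = 15, plateau_biomass = 11.9, plateau_time = 30,
      citrate_rate = 0.6, lipid_max = 0.20,
      reconsumption = FALSE, reconsumption_rate = 0.25,
      dt = 2, t_end = 80, noise_cv = 0.02),
    expression = list(
      n_genes = 3000, n_up = 640, n_down = 290,
      lfc_range = c(1.5, 4), n_replicates = 2,
      depth = 4e6, baseline_meanlog = log(10), baseline_sdlog = 1.2,
      min_planted_fpkm = 5, length_meanlog = log(1500), length_sdlog = 0.4,
      noise = "poisson"))
}

#' Generate a synthetic fermentation time course
#'
#' Piecewise kinetic emulation of the batch cultures: exponential biomass
#' growth at `mu` until the nitrogen-limitation onset, then linear increase
#' to a plateau; substrates decline linearly at their stated rates until
#' depletion; citrate rises after nitrogen limitation and, when the
#' re-consumption flag is set (the oxygen-limited dual-substrate
#' phenotype), declines again after glycerol depletion; ammonium falls to
#' zero at the onset.  Multiplicative Gaussian noise at `noise_cv` is
#' applied to concentrations (0 = noise-free).
#'
#' @param config A [generator_config()] list (the `fermentation` element is
#'   used), or `NULL` for defaults.
#' @param noise_cv Override for the noise coefficient of variation.
#' @param seed Integer seed.
#' @return A [fermentation_time_series()] data frame.
#' @export
synthetic_fermentation <- function(config = NULL, noise_cv = NULL, seed = 1) {
  cfg <- (if (is.null(config)) generator_config(seed) else config)$fermentation
  if (!is.null(noise_cv)) cfg$noise_cv <- noise_cv
  t <- seq(0, cfg$t_end, by = cfg$dt)
  x_onset <- cfg$initial[["biomass"]] * exp(cfg$mu * cfg$n_onset)
  biomass <- ifelse(t <= cfg$n_onset,
                    cfg$initial[["biomass"]] * exp(cfg$mu * t),
                    pmin(x_onset + (cfg$plateau_biomass - x_onset) *
                           (t - cfg$n_onset) / (cfg$plateau_time - cfg$n_onset),
                         cfg$plateau_biomass))
  glycerol <- pmax(cfg$initial[["glycerol"]] - cfg$rates[["glycerol"]] * t, 0)
  glucose <- pmax(cfg$initial[["glucose"]] - cfg$rates[["glucose"]] * t, 0)
  t_glol_dep <- cfg$initial[["glycerol"]] / cfg$rates[["glycerol"]]
  citrate <- pmax(cfg$citrate_rate * (t - cfg$n_onset), 0)
  if (isTRUE(cfg$reconsumption)) {
    peak <- cfg$citrate_rate * (t_glol_dep - cfg$n_onset)
    citrate <- ifelse(t <= t_glol_dep, citrate,
                      pmax(peak - cfg$reconsumption_rate * (t - t_glol_dep), 0))
  }
  ammonium <- pmax(cfg$initial[["ammonium"]] * (1 - t / cfg$n_onset), 0)
  lipid_fraction <- pmin(cfg$lipid_max * t / cfg$n_onset, cfg$lipid_max)
  df <- data.frame(time = t, biomass = biomass, glucose = glucose,
                   glycerol = glycerol, citrate = citrate,
                   lipid_fraction = lipid_fraction, ammonium = ammonium)
  if (cfg$noise_cv > 0) {
    set.seed(seed)
    for (col in c("biomass", "glucose", "glycerol", "citrate"))
      df[[col]] <- pmax(df[[col]] *
                          (1 + stats::rnorm(nrow(df), 0, cfg$noise_cv)), 0)
  }
  fermentation_time_series(df)
}

#' Generate a synthetic two-phase expression table
#'
#' Draws baseline phase-I FPKM levels log-normally, plants up- and
#' down-regulated genes with |log2 fold changes| drawn from `lfc_range`,
#' converts expected FPKM to expected fragment counts through gene lengths
#' and library depth, and (optionally) applies Poisson counting noise.
#'
#' @param config A [generator_config()] list, or `NULL` for defaults.
#' @param noise `"poisson"` or `"none"` (expected counts); overrides the
#'   config when given.
#' @param seed Integer seed.
#' @return An [expression_table()] with attribute `"planted"` (data frame
#'   of gene, class) recording the ground truth.
#' @export
synthetic_expression <- function(config = NULL, noise = NULL, seed = 1) {
  cfg <- (if (is.null(config)) generator_config(seed) else config)$expression
  if (!is.null(noise)) cfg$noise <- noise
  if (cfg$n_up + cfg$n_down > cfg$n_genes)
    stop("n_up + n_down exceeds n_genes")
  set.seed(seed)
  g <- cfg$n_genes
  gene <- sprintf("GENE%04d", seq_len(g))
  length_b <- pmax(round(stats::rlnorm(g, cfg$length_meanlog, cfg$length_sdlog)), 200)
  fpkm_I <- stats::rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)
  planted <- rep("NSE", g)
  reg <- sample.int(g, cfg$n_up + cfg$n_down)
  up <- reg[seq_len(cfg$n_up)]
  down <- setdiff(reg, up)
  planted[up] <- "up"; planted[down] <- "down"
  fpkm_I[reg] <- pmax(fpkm_I[reg], cfg$min_planted_fpkm)
  lfc <- numeric(g)
  lfc[up] <- stats::runif(cfg$n_up, cfg$lfc_range[1], cfg$lfc_range[2])
  lfc[down] <- -stats::runif(cfg$n_down, cfg$lfc_range[1], cfg$lfc_range[2])
  fpkm_II <- fpkm_I * 2^lfc
  nrep <- cfg$n_replicates
  expected <- cbind(
    matrix(rep(fpkm_I * (length_b / 1000) * (cfg$depth / 1e6), nrep), ncol = nrep),
    matrix(rep(fpkm_II * (length_b / 1000) * (cfg$depth / 1e6), nrep), ncol = nrep))
  counts <- if (identical(cfg$noise, "poisson"))
    matrix(stats::rpois(length(expected), expected), nrow = g)
  else round(expected)
  phase <- rep(c("I", "II"), each = nrep)
  colnames(counts) <- paste0("phase", phase, "_r", rep(seq_len(nrep), 2))
  tbl <- expression_table(counts, lengths = length_b, phase = phase,
                          gene_ids = gene,
                          total_mapped = rep(cfg$depth, 2 * nrep))
  attr(tbl, "planted") <- data.frame(gene = gene, class = planted,
                                     log2fc = lfc, stringsAsFactors = FALSE)
  tbl
}
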