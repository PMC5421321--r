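# Flux estimation from measured fragment MDVs by variance-weighted
# nonlinear least squares (Levenberg-Marquardt, multistart).

#' Assemble a measurement set
#'
#' @param fragment Character vector of fragment ids (one entry per mass).
#' @param mass Integer mass shifts (`0 ... n`).
#' @param value Observed mass fractions.
#' @param sd Per-mass standard deviations (mol fraction); a single value is
#'   recycled.
#' @return A data frame of class `mdv_measurements`.
#' @export
mdv_measurements <- function(fragment, mass, value, sd = 0.004) {
  df <- data.frame(fragment = fragment, mass = as.integer(mass),
                   value = value, sd = sd, stringsAsFactors = FALSE)
  if (any(df$sd <= 0)) stop("measurement sd must be positive")
  sums <- tapply(df$value, df$fragment, sum)
  if (any(abs(sums - 1) > 0.02))
    stop("observed MDV(s) do not sum to 1 within 0.02: ",
         paste(names(sums)[abs(sums - 1) > 0.02], collapse = ", "))
  class(df) <- c("mdv_measurements", "data.frame")
  df
}

# Weighted residuals of one experiment.  Measured MDVs are renormalized to
# sum 1, which makes the noise component along the MDV direction
# unobservable; projecting it out of the residual restores the nominal
# iid-Gaussian error model (SSR ~ chi-square with one degree of freedom per
# fragment lost, matching the dof accounting).
residuals_for <- function(emu_net, flux, inputs, meas) {
  sim <- simulate_mdvs(emu_net, flux, inputs = inputs)
  out <- numeric(nrow(meas))
  for (fr in unique(meas$fragment)) {
    rows <- which(meas$fragment == fr)
    m <- sim[[fr]][meas$mass[rows] + 1]
    r <- m - meas$value[rows]
    r <- r - (sum(r * m) / sum(m * m)) * m
    out[rows] <- r / meas$sd[rows]
  }
  out
}

#' Estimate fluxes from isotope-labeling measurements
#'
#' Minimizes the variance-weighted sum of squared residuals between
#' simulated and observed fragment mass fractions over the free net fluxes
#' (box-bounded) and the exchange fluxes of the reversible reactions
#' (optimizer variable `x` in `[0, 1)`, mapped to `[0, Inf)` as
#' `x / (1 - x)`).  Parallel labeling experiments are fitted jointly by
#' stacking their residuals.  The best of `n_starts` seeded multistarts is
#' returned; starts are drawn with the feasible-flux sampler.
#'
#' @param network A `flux_network`.
#' @param emu_net The matching `emu_network` (see [emu_decompose()]).
#' @param experiments A list of experiments, each `list(mixture, meas)`
#'   with a `tracer_mixture` and an `mdv_measurements` table.  A single
#'   experiment may be passed directly.
#' @param n_starts Number of multistarts (>= 1).
#' @param seed Integer seed controlling the starts (fits are reproducible
#'   given `seed`, `n_starts` and tolerances).
#' @param bounds Box for irreversible free net fluxes (reversible free
#'   fluxes use the symmetric box).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param param Optional precomputed [flux_parameterization()].
#' @return An object of class `flux_fit`: `flux` (normalized `flux_map`),
#'   `free_flux_estimates`, `exchange_estimates`, `ssr`, `dof`,
#'   `converged`, `n_restarts_used`, `seed`.
#' @export
fit_fluxes <- function(network, emu_net, experiments, n_starts = 3, seed = 1,
                       bounds = c(0, 300), maxiter = 80, param = NULL) {
  if (!is.null(experiments$mixture)) experiments <- list(experiments)
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (is.null(param)) param <- flux_parameterization(network)
  nfree <- param$nfree
  rev_ids <- param$reversible
  nex <- length(rev_ids)
  free_rev <- param$free %in% rev_ids
  lower <- c(ifelse(free_rev, -bounds[2], bounds[1]), rep(0, nex))
  upper <- c(rep(bounds[2], nfree), rep(0.995, nex))

  inputs <- lapply(experiments, function(ex) emu_input_mdvs(emu_net, ex$mixture))
  n_masses <- sum(vapply(experiments, function(ex) nrow(ex$meas), 0L))
  n_indep <- sum(vapply(experiments, function(ex)
    nrow(ex$meas) - length(unique(ex$meas$fragment)), 0L))
  dof <- n_indep - (nfree + nex)

  penalty_scale <- 1e3
  make_flux <- function(par) {
    ex <- stats::setNames(par[nfree + seq_len(nex)], rev_ids)
    ex <- ex / (1 - ex)
    complete_flux(param, par[seq_len(nfree)], exchange = ex)
  }
  resid_fn <- function(par) {
    flux <- make_flux(par)
    pen <- penalty_scale * pmin(flux$net[param$irreversible], 0)
    meas_res <- tryCatch(
      unlist(lapply(seq_along(experiments), function(k)
        residuals_for(emu_net, flux, inputs[[k]], experiments[[k]]$meas))),
      error = function(e) rep(1e3, n_masses))
    c(meas_res, pen)
  }

  draw_start <- function(s) {
    fm <- tryCatch(random_feasible_fluxmap(network, seed = s, param = param),
                   error = function(e) NULL)
    if (is.null(fm)) return(NULL)
    ex <- fm$exchange[rev_ids]
    c(fm$net[param$free], ex / (1 + ex))
  }

  best <- NULL
  used <- 0L
  for (k in seq_len(n_starts)) {
    start <- draw_start(seed * 1000L + k)
    if (is.null(start)) next
    start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
    used <- used + 1L
    # stage 1: net free fluxes only, exchange frozen at the start draw --
    # the net fluxes dominate the MDVs, so this lands in the right basin
    # before the full (and flatter) joint problem is polished
    x0 <- start[nfree + seq_len(nex)]
    s1 <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = start[seq_len(nfree)], lower = lower[seq_len(nfree)],
      upper = upper[seq_len(nfree)],
      fn = function(p) resid_fn(c(p, x0)),
      control = minpack.lm::nls.lm.control(maxiter = min(maxiter, 60),
                                           nprint = 0))),
      error = function(e) NULL)
    if (is.null(s1)) next
    # stage 2: joint net + exchange fit from the stage-1 optimum
    res <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = c(s1$par, x0), lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                           ptol = 1e-10, nprint = 0))),
      error = function(e) NULL)
    if (is.null(res)) next
    dev <- sum(res$fvec^2)
    if (is.null(best) || dev < best$dev)
      best <- list(dev = dev, par = res$par, info = res$info)
    if (best$dev < 1e-8) break   # an (essentially) exact fit cannot improve
  }
  if (is.null(best))
    return(structure(list(flux = NULL, converged = FALSE, ssr = Inf,
                          dof = dof, n_restarts_used = used, seed = seed),
                     class = "flux_fit"))
  flux <- make_flux(best$par)
  meas_ssr <- sum(unlist(lapply(seq_along(experiments), function(k)
    residuals_for(emu_net, flux, inputs[[k]], experiments[[k]]$meas)))^2)
  structure(list(
    flux = flux,
    free_flux_estimates = stats::setNames(best$par[seq_len(nfree)], param$free),
    exchange_estimates = {
      x <- best$par[nfree + seq_len(nex)]
      stats::setNames(x / (1 - x), rev_ids)
    },
    ssr = meas_ssr, dof = dof,
    converged = best$info %in% 1:4, n_restarts_used = used, seed = seed,
    param = param), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit>", if (isTRUE(x$converged)) "converged" else "NOT converged",
      sprintf(" SSR %.4g on %d dof (%d starts)\n", x$ssr, x$dof, x$n_restarts_used))
  if (!is.null(x$free_flux_estimates)) {
    cat("  free net fluxes (% of uptake):\n")
    print(round(x$free_flux_estimates, 2))
  }
  invisible(x)
}

#' Chi-square goodness-of-fit test of a flux fit
#'
#' Under a correctly specified model and measurement variances, the SSR is
#' approximately chi-square distributed with `dof` degrees of freedom; the
#' fit is accepted when the SSR does not exceed the upper `alpha` quantile.
#'
#' @param fit A `flux_fit`.
#' @param alpha Test level (default 0.05).
#' @return List with `accept`, `p_value`, `ssr`, `dof`, `threshold`.
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  if (is.null(fit$dof) || fit$dof < 1)
    stop("goodness-of-fit requires dof >= 1 (model is over-parameterized)")
  thr <- stats::qchisq(1 - alpha, fit$dof)
  list(accept = fit$ssr <= thr,
       p_value = stats::pchisq(fit$ssr, fit$dof, lower.tail = FALSE),
       ssr = fit$ssr, dof = fit$dof, threshold = thr)
}

#' Oxidative pentose phosphate pathway split of a flux map
#'
#' Returns the net flux entering the oxidative PPP (the G6P dehydrogenase
#' step) as a percentage of total C-source uptake.  The map must already be
#' normalized to uptake = 100.
#'
#' @param flux A normalized `flux_map`.
#' @return Numeric scalar (% of uptake).
#' @export
ppp_split <- function(flux) {
  if (identical(flux$basis, "absolute"))
    stop("flux map must be normalized to the uptake basis; see normalize_fluxes()")
  if (!"g6pdh" %in% names(flux$net))
    stop("flux map has no oxidative-PPP entry reaction (g6pdh)")
  unname(flux$net[["g6pdh"]])
}

#' Parameter-recovery simulation for the PPP split
#'
#' Builds a feasible steady-state flux map on the bundled network of the
#' requested substrate condition with the oxidative-PPP entry pinned to
#' `ppp_flux` (% of uptake), simulates the GC-MS fragment panel under the
#' condition's tracer recipe(s) with Gaussian noise, refits the fluxes, and
#' reports the recovered PPP split.
#'
#' Glucose cultures use the parallel 1-13C and 20% U-13C6 experiments,
#' fitted jointly; glycerol cultures use the 20% U-13C3 tracer.
#'
#' @param condition `"glucose"` or `"glycerol"`.
#' @param ppp_flux True oxidative-PPP entry (% of uptake).
#' @param seed Integer seed for the ground-truth map, the noise and the fit.
#' @param sd Measurement noise (mol fraction, default 0.004).
#' @param n_starts Multistarts for the fit.
#' @return List with `true_ppp`, `recovered_ppp`, `true_flux`, `fit`.
#' @export
ppp_recovery_experiment <- function(condition = c("glucose", "glycerol"),
                                    ppp_flux, seed = 1, sd = 0.004,
                                    n_starts = 3) {
  condition <- match.arg(condition)
  network <- build_yarrowia_network(condition)
  emu_net <- emu_decompose(network)
  param <- flux_parameterization(network)
  truth <- random_feasible_fluxmap(network, seed = seed, param = param,
                                   fixed = c(g6pdh = ppp_flux))
  mixtures <- if (condition == "glucose")
    list(bundled_mixture("glc_1C"), bundled_mixture("glc_U20"))
  else list(bundled_mixture("glol_U20"))
  experiments <- lapply(seq_along(mixtures), function(k)
    list(mixture = mixtures[[k]],
         meas = synthetic_mdv_measurements(emu_net, truth, mixtures[[k]],
                                           sd = sd, seed = seed * 7L + k)))
  fit <- fit_fluxes(network, emu_net, experiments, n_starts = n_starts,
                    seed = seed, param = param, maxiter = 200)
  list(true_ppp = ppp_split(truth), recovered_ppp = ppp_split(fit$flux),
       true_flux = truth, fit = fit)
}
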