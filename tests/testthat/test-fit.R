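branch_setup <- function() {
  net <- toy_network("branch")
  list(net = net,
       emu = emu_decompose(net),
       param = flux_parameterization(net, prefer = "r1"),
       mix = toy_tracer(net, fraction = 0.5, purity = 0.99,
                        natural_abundance = 0.0107, positions = 3))
}

test_that("noise-free measurements are a zero-residual fixed point", {
  s <- branch_setup()
  truth <- random_feasible_fluxmap(s$net, seed = 3, param = s$param,
                                   bounds = c(0, 100))
  meas <- synthetic_mdv_measurements(s$emu, truth, s$mix, sd = 0, seed = 1)
  fit <- fit_fluxes(s$net, s$emu, list(list(mixture = s$mix, meas = meas)),
                    n_starts = 2, seed = 5, param = s$param)
  expect_true(fit$converged)
  expect_lt(fit$ssr, 1e-6)
  expect_lt(abs(fit$free_flux_estimates[["r1"]] - truth$net[["r1"]]) /
              truth$net[["r1"]], 1e-3)
})

test_that("duplicating every measurement row leaves estimates unchanged and doubles SSR", {
  s <- branch_setup()
  truth <- random_feasible_fluxmap(s$net, seed = 7, param = s$param,
                                   bounds = c(0, 100))
  meas <- synthetic_mdv_measurements(s$emu, truth, s$mix, sd = 0.004, seed = 2)
  fit1 <- fit_fluxes(s$net, s$emu, list(list(mixture = s$mix, meas = meas)),
                     n_starts = 1, seed = 5, param = s$param)
  # duplication via a second identical parallel experiment
  fit2 <- fit_fluxes(s$net, s$emu, list(list(mixture = s$mix, meas = meas),
                                        list(mixture = s$mix, meas = meas)),
                     n_starts = 1, seed = 5, param = s$param)
  expect_equal(fit2$free_flux_estimates, fit1$free_flux_estimates,
               tolerance = 1e-6)
  expect_equal(fit2$ssr, 2 * fit1$ssr, tolerance = 1e-6)
})

test_that("SSR is non-increasing in the number of multistarts and fits are reproducible", {
  s <- branch_setup()
  truth <- random_feasible_fluxmap(s$net, seed = 11, param = s$param,
                                   bounds = c(0, 100))
  meas <- synthetic_mdv_measurements(s$emu, truth, s$mix, sd = 0.004, seed = 3)
  exps <- list(list(mixture = s$mix, meas = meas))
  f1 <- fit_fluxes(s$net, s$emu, exps, n_starts = 1, seed = 9, param = s$param)
  f3 <- fit_fluxes(s$net, s$emu, exps, n_starts = 3, seed = 9, param = s$param)
  expect_lte(f3$ssr, f1$ssr + 1e-10)
  f1b <- fit_fluxes(s$net, s$emu, exps, n_starts = 1, seed = 9, param = s$param)
  expect_identical(f1$free_flux_estimates, f1b$free_flux_estimates)
  expect_identical(f1$ssr, f1b$ssr)
})

test_that("chi-square test accepts perfect fits and rejects gross misfits", {
  perfect <- structure(list(ssr = 0, dof = 20), class = "flux_fit")
  g <- goodness_of_fit(perfect, 0.05)
  expect_true(g$accept)
  expect_equal(g$p_value, 1)
  bad <- structure(list(ssr = 200, dof = 20), class = "flux_fit")
  expect_false(goodness_of_fit(bad, 0.05)$accept)
  over <- structure(list(ssr = 1, dof = 0), class = "flux_fit")
  expect_error(goodness_of_fit(over), "dof")
})

test_that("SSR of correctly specified fits is chi-square distributed", {
  s <- branch_setup()
  ssrs <- numeric(50)
  for (k in 1:50) {
    truth <- random_feasible_fluxmap(s$net, seed = k, param = s$param,
                                     bounds = c(0, 100))
    meas <- synthetic_mdv_measurements(s$emu, truth, s$mix, sd = 0.004,
                                       seed = k + 300)
    fit <- fit_fluxes(s$net, s$emu, list(list(mixture = s$mix, meas = meas)),
                      n_starts = 1, seed = k, param = s$param)
    ssrs[k] <- fit$ssr
    dof <- fit$dof
  }
  expect_gte(mean(ssrs), dof * 0.7)
  expect_lte(mean(ssrs), dof * 1.3)
})

test_that("the PPP split reads the oxidative-PPP entry of a normalized map", {
  net <- build_yarrowia_network("glucose")
  param <- flux_parameterization(net)
  fm <- random_feasible_fluxmap(net, seed = 1, param = param,
                                fixed = c(g6pdh = 35))
  expect_equal(ppp_split(fm), 35)
  expect_equal(ppp_split(normalize_fluxes(fm, "glc_upt")), 35)
  zero <- random_feasible_fluxmap(net, seed = 2, param = param,
                                  fixed = c(g6pdh = 0))
  expect_equal(ppp_split(zero), 0)
  absolute <- flux_map(fm$net, fm$exchange, basis = "absolute")
  expect_error(ppp_split(absolute), "normalized")
})

test_that("free net fluxes are recovered across seeded ground-truth maps", {
  net <- build_yarrowia_network("glucose")
  emu <- emu_decompose(net)
  param <- flux_parameterization(net)
  mixes <- list(bundled_mixture("glc_1C"), bundled_mixture("glc_U20"))
  errs <- c()
  for (k in 1:20) {
    truth <- random_feasible_fluxmap(net, seed = 100 + k, param = param)
    exps <- lapply(seq_along(mixes), function(j)
      list(mixture = mixes[[j]],
           meas = synthetic_mdv_measurements(emu, truth, mixes[[j]],
                                             sd = 0.004, seed = k * 13 + j)))
    fit <- suppressWarnings(
      fit_fluxes(net, emu, exps, n_starts = 4, seed = k, param = param,
                 maxiter = 120))
    errs <- c(errs, abs(fit$free_flux_estimates - truth$net[param$free]))
  }
  expect_lte(median(errs), 2)
})

test_that("biomass-coefficient perturbations leave the PPP split stable", {
  # fitted fluxes should be insensitive to +/-20% on the (non-measured)
  # biomass precursor coefficients
  net <- build_yarrowia_network("glucose")
  emu <- emu_decompose(net)
  param <- flux_parameterization(net)
  truth <- random_feasible_fluxmap(net, seed = 21, param = param,
                                   fixed = c(g6pdh = 35))
  mix <- bundled_mixture("glc_1C")
  meas <- synthetic_mdv_measurements(emu, truth, mix, sd = 0, seed = 1)
  perturbed <- net
  perturbed$reactions$bm$lhs$coef <- perturbed$reactions$bm$lhs$coef *
    c(1.2, 0.8, 1.2, 0.8, 1.2, 0.8, 1.2, 0.8, 1.2, 0.8)
  emu_p <- emu_decompose(perturbed)
  param_p <- flux_parameterization(perturbed)
  fit <- suppressWarnings(
    fit_fluxes(perturbed, emu_p, list(list(mixture = mix, meas = meas)),
               n_starts = 2, seed = 3, param = param_p))
  expect_lt(abs(ppp_split(fit$flux) - 35), 2)
})
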