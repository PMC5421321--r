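toy_flux <- function(net, seed = 1, ...) {
  random_feasible_fluxmap(net, seed = seed, bounds = c(0, 80),
                          exch_range = c(0, 3), ...)
}

test_that("decomposition of a linear chain yields three EMUs and no convolutions", {
  net <- toy_network("chain")
  emu <- emu_decompose(net)
  expect_equal(emu$n_emus, 3L)
  expect_true(all(emu$size == 2L))
  n_conv <- sum(vapply(emu$levels, function(l)
    sum(lengths(l$t_src) > 1), 0L))
  expect_equal(n_conv, 0L)
})

test_that("a condensation reaction produces exactly one convolution transition", {
  net <- toy_network("condense")
  emu <- emu_decompose(net)
  n_conv <- sum(vapply(emu$levels, function(l)
    sum(lengths(l$t_src) > 1), 0L))
  expect_equal(n_conv, 1L)
})

test_that("EMU system size matches the independent dependency-closure oracle", {
  # frozen counts from the closure oracle, recomputed here
  frozen <- c(glucose = 226L, glycerol = 225L, dual = 238L)
  for (mode in names(frozen)) {
    net <- build_yarrowia_network(mode)
    emu <- emu_decompose(net)
    oracle <- emu_closure_ids(net, net$fragments)
    expect_identical(emu$n_emus, length(oracle))
    expect_identical(emu$n_emus, frozen[[mode]])
    expect_setequal(emu$ids, oracle)
  }
})

test_that("label passes unchanged through a linear pathway", {
  net <- toy_network("chain")
  emu <- emu_decompose(net)
  fm <- complete_flux(flux_parameterization(net, prefer = character(0)),
                      numeric(0))
  mix <- toy_tracer(net, fraction = 0.4, purity = 1, natural_abundance = 0)
  sim <- simulate_mdvs(emu, fm, mix)
  expect_equal(sim$C, substrate_emu_mdv(mix, "A.e", 1:2))
})

test_that("a rejoining branch point mixes branch MDVs with flux weights", {
  net <- toy_network("branch")
  param <- flux_parameterization(net, prefer = "r1")
  mix <- toy_tracer(net, fraction = 1, purity = 1, natural_abundance = 0,
                    positions = 3)
  emu <- emu_decompose(net)
  for (f1 in c(20, 50, 80)) {
    fm <- complete_flux(param, c(r1 = f1))
    sim <- simulate_mdvs(emu, fm, mix)
    f3 <- fm$net[["r3"]]
    # branch 1 carries the intact labeled substrate (M+1); branch 2 loses
    # the labeled C3 to CO2 and regains an unlabeled carbon (M+0)
    expected <- (f1 * c(0, 1, 0, 0) + f3 * c(1, 0, 0, 0)) / (f1 + f3)
    expect_equal(sim$P, expected, tolerance = 1e-12)
  }
})

test_that("EMU simulation reproduces exhaustive isotopomer enumeration", {
  worst <- 0
  for (nm in toy_network_names()) {
    net <- toy_network(nm)
    emu <- emu_decompose(net)
    param <- flux_parameterization(net, prefer = c("r1", "r5"))
    for (seed in 1:2) {
      fm <- toy_flux(net, seed = seed, param = param)
      for (tr in list(
        toy_tracer(net, fraction = 0.5, purity = 1, natural_abundance = 0.0107),
        toy_tracer(net, fraction = 0.3, purity = 0.99, natural_abundance = 0.0107,
                   positions = 1:2))) {
        sim <- simulate_mdvs(emu, fm, tr)
        state <- isotopomer_simulate(net, fm, tr)
        for (fr in net$fragments) {
          oracle <- iso_fragment_mdv(state, net, fr)
          worst <- max(worst, max(abs(oracle - sim[[fr$id]])))
        }
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("simulated MDVs are simplex-valued and scale-invariant in flux", {
  net <- build_yarrowia_network("glucose")
  emu <- emu_decompose(net)
  mix <- bundled_mixture("glc_1C")
  for (seed in 1:5) {
    fm <- random_feasible_fluxmap(net, seed = seed)
    sim <- simulate_mdvs(emu, fm, mix)
    for (m in sim) {
      expect_true(all(m >= -1e-12))
      expect_equal(sum(m), 1, tolerance = 1e-9)
    }
    scaled <- flux_map(fm$net * 3.7, fm$exchange * 3.7, basis = fm$basis)
    sim2 <- simulate_mdvs(emu, scaled, mix)
    expect_equal(sim2, sim, tolerance = 1e-10)
  }
})

test_that("13C entering substrates balances 13C leaving products, biomass and CO2", {
  cases <- list(list("glucose", "glc_1C"), list("glucose", "glc_U20"),
                list("glycerol", "glol_U20"), list("dual", "dual_mix"))
  for (cs in cases) {
    net <- build_yarrowia_network(cs[[1]])
    fm <- random_feasible_fluxmap(net, seed = 4)
    bal <- carbon_labeling_balance(net, fm, bundled_mixture(cs[[2]]))
    expect_lt(bal$relative_gap, 1e-6)
  }
})

test_that("a disconnected EMU pool raises a singular-system error", {
  net <- toy_network("branch")
  v <- stats::setNames(c(100, 100, 0, 0, 0, 0, 100), names(net$reactions))
  fm <- flux_map(v, network = net)
  emu <- emu_decompose(net)
  mix <- toy_tracer(net, fraction = 0.5, purity = 1, natural_abundance = 0)
  expect_error(simulate_mdvs(emu, fm, mix), "singular|no flux")
})

test_that("natural-abundance correction matches its binomial definition", {
  expect_equal(apply_natural_abundance_correction(c(0.3, 0.7), 1, "uncorrect",
                                                  abundance = 0),
               c(0.3, 0.7))
  expect_equal(apply_natural_abundance_correction(c(1, 0), 1, "uncorrect"),
               c(0.9893, 0.0107))
  # oracle: uncorrection is convolution of each pure-j state with its
  # binomial natural-abundance envelope
  set.seed(42)
  for (n in c(2, 4, 6)) {
    x <- stats::runif(n + 1); x <- x / sum(x)
    oracle <- numeric(n + 1)
    for (j in 0:n)
      oracle <- oracle + x[j + 1] *
        c(rep(0, j), stats::dbinom(0:(n - j), n - j, 0.0107))
    un <- apply_natural_abundance_correction(x, n, "uncorrect")
    expect_equal(un, oracle, tolerance = 1e-12)
    # round trip
    back <- apply_natural_abundance_correction(un, n, "correct")
    expect_equal(back, x, tolerance = 1e-10)
  }
  expect_error(apply_natural_abundance_correction(c(0.5, 0, 0.5), 2, "correct"),
               "negative")
})
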