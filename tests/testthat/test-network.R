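test_that("bundled networks have the stated topology", {
  glc <- build_yarrowia_network("glucose")
  # cytosolic acetyl-CoA is formed only through ATP:citrate lyase
  aca_producers <- names(Filter(function(rx) "ACA.c" %in% rx$rhs$met,
                                glc$reactions))
  expect_identical(aca_producers, "acl")
  expect_false("g3pdh" %in% names(glc$reactions))

  glol <- build_yarrowia_network("glycerol")
  expect_true("g3pdh" %in% names(glol$reactions))
  expect_identical(glol$reactions$g3pdh$lhs$met, "G3P.c")
  expect_identical(glol$reactions$g3pdh$rhs$met, "DHAP.c")

  dual <- build_yarrowia_network("dual")
  expect_length(dual$uptakes, 2L)
  expect_setequal(dual$inputs, c("GLC.e", "GLOL.e"))
})

test_that("bundled networks conserve carbon and declared degrees of freedom", {
  for (mode in c("glucose", "glycerol", "dual")) {
    net <- build_yarrowia_network(mode)
    expect_identical(validate_carbon_balance(net), character(0))
    expect_identical(null_space_dim(net), net$nfree_declared)
  }
  for (nm in toy_network_names())
    expect_identical(validate_carbon_balance(toy_network(nm)), character(0))
})

test_that("carbon-balance validation reports constructed defects", {
  net <- build_yarrowia_network("glucose")
  # PDH without its CO2 product loses a carbon
  broken <- net
  broken$reactions$pdh$rhs <- broken$reactions$pdh$rhs[1, , drop = FALSE]
  broken$reactions$pdh$amap$rhs <- "bc"
  v <- validate_carbon_balance(broken)
  expect_length(v, 1L)
  expect_match(v, "pdh")
  expect_match(v, "not carried")
  # duplicated product label
  broken2 <- net
  broken2$reactions$tpi$amap$rhs <- "abb"
  v2 <- validate_carbon_balance(broken2)
  expect_true(any(grepl("tpi", v2)))
  expect_true(any(grepl("duplicated product", v2)))
})

test_that("steady-state residuals behave as S %*% v", {
  net <- build_yarrowia_network("glucose")
  zero <- flux_map(stats::setNames(rep(0, length(net$reactions)),
                                   names(net$reactions)), network = net)
  expect_equal(max(abs(steady_state_residual(net, zero))), 0)

  fm <- random_feasible_fluxmap(net, seed = 2)
  expect_lt(attr(steady_state_residual(net, fm), "max_abs"), 1e-9)

  # inflating one producer of cytosolic pyruvate by 1 shows up at PYR.c
  bad <- fm
  bad$net[["pyk"]] <- bad$net[["pyk"]] + 1
  r <- steady_state_residual(net, bad)
  expect_equal(unname(r[["PYR.c"]]), 1)

  incomplete <- fm
  incomplete$net <- fm$net[-match("pyk", names(fm$net))]
  expect_error(steady_state_residual(net, incomplete), "pyk")
})

test_that("flux normalization scales to uptake = 100 and is idempotent", {
  net <- build_yarrowia_network("glucose")
  fm <- random_feasible_fluxmap(net, seed = 5)
  abs_map <- flux_map(fm$net * 0.025, fm$exchange * 0.025)  # uptake 2.5
  nrm <- normalize_fluxes(abs_map, "glc_upt")
  expect_equal(unname(nrm$net[["glc_upt"]]), 100)
  # proportionality: every flux is 100 * v / v_uptake
  expect_equal(nrm$net, 100 * abs_map$net / abs_map$net[["glc_upt"]])
  expect_equal(normalize_fluxes(nrm, "glc_upt")$net, nrm$net)
  # steady state preserved
  expect_lt(attr(steady_state_residual(net, nrm), "max_abs"), 1e-9)
  expect_error(normalize_fluxes(flux_map(c(glc_upt = 0)), "glc_upt"), "positive")
})

test_that("dual-substrate maps normalize to summed uptake = 100", {
  net <- build_yarrowia_network("dual")
  fm <- random_feasible_fluxmap(net, seed = 3)
  nrm <- normalize_fluxes(fm, net$uptakes)
  # summation oracle
  expect_equal(sum(vapply(net$uptakes, function(u) nrm$net[[u]], 0)), 100)
})

test_that("free-flux completion reproduces sampled maps exactly", {
  for (mode in c("glucose", "dual")) {
    net <- build_yarrowia_network(mode)
    param <- flux_parameterization(net)
    fm <- random_feasible_fluxmap(net, seed = 9, param = param)
    back <- complete_flux(param, fm$net[param$free], exchange = fm$exchange)
    expect_equal(back$net, fm$net, tolerance = 1e-10)
  }
})

test_that("network config files round-trip through the reader and writer", {
  net <- build_yarrowia_network("glucose")
  tmp <- tempfile(fileext = ".txt")
  write_network_config(net, tmp)
  net2 <- read_network_config(tmp)
  expect_identical(names(net2$reactions), names(net$reactions))
  expect_identical(net2$inputs, net$inputs)
  expect_identical(net2$symmetric, net$symmetric)
  for (id in names(net$reactions))
    expect_identical(net2$reactions[[id]], net$reactions[[id]])
  # writing the reread network reproduces the same text
  expect_identical(write_network_config(net2), write_network_config(net))
})

test_that("the reader rejects malformed configurations", {
  expect_error(read_network_config(text = c("input: A.e", "r1: A.e -> B.q | a -> a | irr")),
               "compartment")
  expect_error(read_network_config(text = c("input: A.e", "r1: A.e -> B.c | irr")),
               "malformed")
  expect_error(read_network_config(
    text = c("input: A.e", "r1: A.e -> B.c | ab -> ab | irr",
             "r1: B.c -> C.e | ab -> ab | irr")), "duplicate")
})
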