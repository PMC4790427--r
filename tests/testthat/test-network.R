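test_that("default network carries the measured pool sizes", {
  net <- default_net()
  glu <- net$pools$Glu_n$concentration + net$pools$Glu_g$concentration
  asp <- net$pools$Asp_n$concentration + net$pools$Asp_g$concentration
  expect_equal(glu, 8.4)
  expect_equal(net$pools$Gln$concentration, 4.3)
  expect_equal(asp, 2.5)
  # overriding a concentration with its default changes nothing
  net2 <- build_default_network(config = list(Gln = 4.3))
  expect_equal(net2$pools, net$pools)
  expect_error(build_default_network(config = list(Gln = -1)), "positive")
  expect_error(build_default_network(config = list(Foo = 1)), "unknown")
})

test_that("derived fluxes follow the mass-balance formulas", {
  f <- derived_fluxes(flux_set(Vg = 0.10, Vpc = 0.06))
  expect_equal(unname(f$derived["VTCA_g"]), 0.16)
  f <- derived_fluxes(flux_set(Vpdh_n = 0.40, Vg = 0.10, Vpc = 0.06))
  expect_equal(unname(f$derived["CMRglc_ox"]), 0.28)
  expect_equal(unname(f$derived["Vsyn"]),
               unname(f$free["Vnt"] + f$free["Vpc"]))
  expect_equal(unname(f$derived["Vin"]), unname(f$free["Vout"]))
  z <- derived_fluxes(flux_set(0, 0, 0, 0, 0, 0, 0))
  expect_true(all(z$derived == 0))
  # VTCA_g identity holds for arbitrary inputs
  for (i in 1:10) {
    set.seed(i)
    v <- runif(7, 0, 2)
    fi <- derived_fluxes(do.call(flux_set, as.list(v)))
    expect_equal(unname(fi$derived["VTCA_g"]),
                 unname(fi$free["Vg"] + fi$free["Vpc"]))
  }
  expect_error(flux_set(Vnt = -0.1), "nonnegative")
})

test_that("steady-state mass balance closes for any valid flux set", {
  net <- default_net()
  expect_equal(max(abs(validate_mass_balance(net, default_truth_fluxes()))),
               0, tolerance = 1e-12)
  for (i in 1:5) {
    set.seed(100 + i)
    f <- do.call(flux_set, as.list(runif(7, 0, 1)))
    expect_lt(max(abs(validate_mass_balance(net, f))), 1e-12)
  }
})

test_that("doubling Vnt without adjusting Vsyn breaks the Gln balance", {
  net <- default_net()
  v <- flux_values(default_truth_fluxes(), constants = net$constants)
  v[["Vnt"]] <- 2 * v[["Vnt"]]        # Vsyn left at its old value
  res <- validate_mass_balance(net, v)
  # Gln: in Vsyn(0.16) - out (Vnt' + Vefflux) = 0.16 - 0.26
  expect_equal(unname(res["Gln"]), -0.10)
  expect_true(any(abs(res) > 1e-6))
})

test_that("missing flux labels and atom-map errors are reported", {
  net <- default_net()
  v <- flux_values(default_truth_fluxes(), constants = net$constants)
  expect_error(validate_mass_balance(net, v[setdiff(names(v), "Vpc")]),
               "absent")
  expect_error(pool("X", "shared", 9, 1), "n_carbons")
  expect_error(pool("X", "nowhere", 3, 1), "compartment")
  expect_error(
    reaction("r", "V", c(A = 1),
             products = list(B = list(list(weight = 0.7,
                                           map = c("A.1"))))),
    "sum to 1")
})

test_that("atom maps use each product carbon exactly once", {
  net <- default_net()
  for (r in net$reactions) {
    for (q in names(r$products)) {
      nc <- net$pools[[q]]$n_carbons
      for (o in r$products[[q]]) {
        expect_length(o$map, nc)
        src <- o$map[o$map != "*"]
        # per orientation, sources within a substrate are unique
        expect_false(anyDuplicated(src) > 0)
      }
    }
  }
})
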