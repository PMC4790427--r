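test_that("bonded state counts match the combinatorics", {
  # isolated n-carbon pool: n singles + (n-1) bonded pairs + (n-2) triples
  expect_equal(nrow(enumerate_bonded_cumomers(
    isolated_pool_network(5))$states), 12)
  expect_equal(nrow(enumerate_bonded_cumomers(
    isolated_pool_network(2))$states), 3)
  expect_equal(nrow(enumerate_bonded_cumomers(
    isolated_pool_network(5), max_order = 1)$states), 5)
})

test_that("the canonical network yields 133 coupled state equations", {
  sys <- enumerate_bonded_cumomers(default_net())
  expect_equal(nrow(sys$states), 133)
  # intact-fragment filter only removes the glucose fragments spanning
  # the aldolase-cleaved C3-C4 bond
  glc <- sys$states[sys$states$pool == "Glc_b", ]
  expect_equal(nrow(glc), 12)
  expect_false("Glc_b:3,4" %in% glc$key)
  expect_false("Glc_b:2,3,4" %in% glc$key)
  expect_false("Glc_b:3,4,5" %in% glc$key)
})

test_that("precursor-product chain follows the closed-form solution", {
  # A (driven at FE 1) -> B at rate V; B turnover gives 1 - exp(-V t / P)
  pools <- list(pool("A", "input", 1, is_input = TRUE, hot_positions = 1L),
                pool("B", "shared", 1, 2.0))
  names(pools) <- c("A", "B")
  rx <- list(reaction("in", "V", c(A = 1),
                      list(B = list(list(weight = 1, map = "A.1")))),
             reaction("out", "V", c(B = 1)))
  names(rx) <- c("in", "out")
  net <- structure(list(pools = pools, reactions = rx,
                        measured_pools = character(0),
                        observables = list(), constants = c(V = 0.4)),
                   class = "network")
  sys <- build_rhs(net, enumerate_bonded_cumomers(net),
                   natural_abundance = 0)
  inp <- function(t) rep(1, length(t))
  times <- seq(0, 30, by = 1)
  traj <- integrate_system(sys, c(V = 0.4), inp, times,
                           init_natural = FALSE, rtol = 1e-10,
                           atol = 1e-12)
  expect_equal(get_fe(traj, "B", 1), 1 - exp(-0.4 * times / 2.0),
               tolerance = 1e-8)
})

test_that("zero fluxes freeze the system and natural abundance is a fixed point", {
  net <- toy_network()
  sys <- build_cumomer_system(net)
  times <- seq(0, 60, by = 10)
  z <- integrate_system(sys, c(V = 0, Vd = 0, Vloop = 0),
                        function(t) rep(0.7, length(t)), times)
  expect_equal(max(abs(sweep(z$values, 2, z$values[1, ]))), 0)
  # input held at natural abundance: every state stays at na^order
  na <- sys$na
  cs <- integrate_system(sys, c(V = 0.5, Vd = 0.1, Vloop = 0.6),
                         function(t) rep(na, length(t)), times)
  expect_equal(max(abs(sweep(cs$values, 2, na^cs$states$order))), 0,
               tolerance = 1e-9)
})

test_that("steady-state enrichments are bounded by and monotone in the input", {
  net <- toy_network()
  sys <- build_cumomer_system(net)
  times <- c(0, 50, 400, 800)
  fe_ss <- function(level) {
    tr <- integrate_system(sys, c(V = 0.5, Vd = 0.1, Vloop = 0.6),
                           function(t) rep(level, length(t)), times)
    tr$values[length(times), sys$states$order == 1]
  }
  hi <- fe_ss(0.7)
  expect_true(all(hi <= 0.7 + 1e-7))
  lo <- fe_ss(0.4)
  expect_true(all(lo <= hi + 1e-9))
})

test_that("order-1 reduction reproduces the positional subsystem exactly", {
  net <- default_net()
  f <- default_truth_fluxes()
  inp <- input_function(acquisition_spec())
  times <- seq(0, 180, by = 10.6)
  full <- integrate_system(build_cumomer_system(net), f, inp, times)
  red <- integrate_system(build_cumomer_system(net, 1), f, inp, times)
  expect_lt(max(abs(red$values - full$values[, colnames(red$values)])),
            1e-6)
})

test_that("compiled integrator agrees with deSolve and converges in tol", {
  net <- default_net()
  f <- default_truth_fluxes()
  inp <- input_function(acquisition_spec())
  times <- seq(0, 180, by = 21.2)
  sys <- cached("sys3", build_cumomer_system(net))
  a <- integrate_system(sys, f, inp, times, engine = "cpp")
  b <- integrate_system(sys, f, inp, times, engine = "r",
                        rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(a$values - b$values)), 1e-5)
  # halving the tolerance moves the solution by less than 10 * rtol
  c1 <- integrate_system(sys, f, inp, times, rtol = 1e-6, atol = 1e-8)
  c2 <- integrate_system(sys, f, inp, times, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(c1$values - c2$values)), 10 * 1e-6)
})

test_that("containment inequalities hold along the trajectories", {
  net <- default_net()
  sys <- cached("sys3", build_cumomer_system(net))
  traj <- integrate_system(sys, default_truth_fluxes(),
                           input_function(acquisition_spec()),
                           seq(0, 180, by = 10.6))
  st <- sys$states
  for (i in which(st$order > 1)) {
    pos <- st$first[i] + seq_len(st$order[i]) - 1L
    for (drop in c(1, length(pos))) {
      sub <- pos[-drop]
      key <- paste0(st$pool[i], ":", paste(sub, collapse = ","))
      if (!key %in% colnames(traj$values)) next
      expect_true(all(traj$values[, st$key[i]] <=
                        traj$values[, key] + 1e-8),
                  label = paste("containment", st$key[i], "<=", key))
    }
  }
  expect_true(all(traj$values >= -1e-8 & traj$values <= 1 + 1e-8))
})

test_that("untracked or non-adjacent sources raise construction errors", {
  # consumer requires a fragment the enumeration does not track:
  # force it by mapping non-adjacent substrate carbons onto adjacent
  # product carbons
  pools <- list(pool("A", "shared", 3, 1), pool("B", "shared", 2, 1))
  names(pools) <- c("A", "B")
  rx <- list(
    reaction("bad", "V", c(A = 1),
             list(B = list(list(weight = 1, map = c("A.1", "A.3"))))),
    reaction("keep", "V", c(B = 1),
             list(A = list(list(weight = 1,
                                map = c("B.1", "B.2", "*"))))))
  names(rx) <- c("bad", "keep")
  net <- structure(list(pools = pools, reactions = rx,
                        measured_pools = "B", observables = list(),
                        constants = c(V = 1)), class = "network")
  expect_error(build_rhs(net, enumerate_bonded_cumomers(net)),
               "non-adjacent")
})
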