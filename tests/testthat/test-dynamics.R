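test_that("flux decomposition matches hand computation on the two-reef toy", {
  lk <- build_links(toy_pair())
  p <- model_params(r = 0.2, s = 1)
  fl <- migration_fluxes(c(1, 0.01), lk, p)
  expect_equal(fl$growth, c(0, 0.2 * 0.01 * 0.99))
  expect_equal(fl$emigration, c(0.2, 0.002))
  expect_equal(fl$immigration, c(0.002, 0.2))
  d <- metapop_derivative(c(1, 0.01), lk, p)
  expect_equal(d, c(-0.198, 0.19998))

  # s = 0 annihilates migration in every mode
  for (mode in c("conservative", "pool", "literal")) {
    fl0 <- migration_fluxes(c(0.3, 0.8), lk,
                            model_params(s = 0, migration_mode = mode))
    expect_equal(fl0$emigration, c(0, 0))
    expect_equal(fl0$immigration, c(0, 0))
  }
})

test_that("conservative-mode migration is globally mass balanced", {
  set.seed(21)
  for (rep in 1:20) {
    nd <- small_strip(20, seed = rep)
    lk <- build_links(nd)
    sub <- sample_links(lk, max(1, rpois(1, nrow(lk) / 2)))
    x <- runif(20, 0, 1.5)
    fl <- migration_fluxes(x, sub, model_params(s = runif(1)))
    expect_lt(abs(sum(fl$immigration) - sum(fl$emigration)), 1e-10)
  }
})

test_that("the printed (literal) closure is not mass conserving", {
  lk <- build_links(toy_triangle())
  p <- model_params(r = 0.2, s = 1, migration_mode = "literal")
  x <- c(1, 1, 1)
  fl <- migration_fluxes(x, lk, p)
  expect_equal(fl$k, c(1, 1, 1))
  expect_equal(fl$x_tilde, 0.6)
  expect_equal(metapop_derivative(x, lk, p), rep(-0.2 + 0.6, 3))
  expect_gt(sum(fl$immigration) - sum(fl$emigration), 1)
})

test_that("all-ones is the no-migration fixed point", {
  lk <- build_links(toy_pair())
  p <- model_params(s = 0)
  expect_equal(metapop_derivative(c(1, 1), lk, p), c(0, 0))
  tr <- integrate_metapop(c(1, 1), lk, p, horizon = 20)
  expect_equal(max(abs(tr$X - 1)), 0)
})

test_that("RK4 reproduces the logistic closed form at every checkpoint", {
  # isolated reefs: each follows the scalar logistic exactly
  lk <- build_links(reef_nodes(c(0, 10), c(0, 0)))  # no links
  p <- model_params(r = 0.2, s = 0, dt = 0.05)
  tr <- integrate_metapop(c(0.01, 0.01), lk, p, horizon = 60)
  err <- max(abs(tr$X[, 1] - logistic_closed(0:60)))
  expect_lt(err, 1e-6)
  expect_equal(logistic_time(0.95), 37.6984, tolerance = 1e-4)
})

test_that("halving dt barely changes checkpoints, at fourth-order rate", {
  lk <- build_links(toy_pair())
  run <- function(dt) integrate_metapop(c(1, 0.01), lk,
                                        model_params(s = 1, dt = dt),
                                        horizon = 20)$X
  expect_lt(max(abs(run(0.05) - run(0.025))), 1e-8)

  # error vs closed form on the isolated logistic shrinks ~16x per halving
  iso <- build_links(reef_nodes(c(0, 10), c(0, 0)))
  err_at <- function(dt) {
    tr <- integrate_metapop(c(0.01, 0.01), iso,
                            model_params(s = 0, dt = dt), horizon = 30)
    max(abs(tr$X[, 1] - logistic_closed(0:30)))
  }
  ratio <- err_at(0.5) / err_at(0.25)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("compiled integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  nd <- small_strip(15, seed = 9)
  lk <- build_links(nd)
  p <- model_params(s = 0.7)
  x0 <- runif(15, 0.2, 1)
  tr <- integrate_metapop(x0, lk, p, horizon = 25)
  ode <- deSolve::rk4(y = x0, times = seq(0, 25, by = 0.05), parms = NULL,
                      func = function(t, y, parms)
                        list(metapop_derivative(y, lk, p)))
  checkpoints <- ode[match(0:25, ode[, 1]), -1, drop = FALSE]
  expect_lt(max(abs(tr$X - checkpoints)), 1e-8)
})

test_that("biomass never goes negative and stays finite", {
  nd <- small_strip(20, seed = 13)
  lk <- build_links(nd)
  p <- model_params(s = 1)
  x0 <- rep(1, 20); x0[1:10] <- 0
  tr <- integrate_metapop(x0, lk, p, horizon = 50)
  expect_true(all(tr$X >= 0))
  expect_true(all(is.finite(tr$X)))
})

test_that("relaxation returns a genuine fixed point", {
  p0 <- model_params(s = 0)
  lk <- build_links(toy_pair())
  eq0 <- relax_to_equilibrium(lk, p0)
  expect_equal(eq0$state, c(1, 1))
  expect_equal(eq0$time, 0)

  # asymmetric degree: hub linked to two leaves that only link back to it
  nd <- reef_nodes(c(0, 0.15, -0.15), c(0, 0, 0))  # leaves 0.3 apart: no leaf-leaf link
  lk3 <- build_links(nd)
  expect_equal(nrow(lk3), 4)
  p <- model_params(s = 1)
  eq <- relax_to_equilibrium(lk3, p)
  expect_lt(eq$residual, p$burn_in_tol)
  expect_gt(max(abs(eq$state - 1)), 1e-3)
  # re-integration from the equilibrium stays put
  tr <- integrate_metapop(eq$state, lk3, p, horizon = 50)
  expect_lt(max(abs(sweep(tr$X, 2, eq$state))), 1e-6)
})

test_that("the divergent literal closure is reported by mode name", {
  nd <- small_strip(12, seed = 2)
  lk <- build_links(nd)
  p <- model_params(s = 1, migration_mode = "literal", t_max = 200)
  expect_error(integrate_metapop(rep(1, 12), lk, p, horizon = 200), "literal")
})

test_that("recovery horizons scale exactly as 1/r when reefs are isolated", {
  # logistic time change of variables: scaling r by c scales time by 1/c
  t1 <- logistic_time(0.95, r = 0.2) / logistic_time(0.95, r = 0.15)
  expect_equal(t1, 0.15 / 0.2, tolerance = 1e-12)
  lk <- build_links(reef_nodes(c(0, 10), c(0, 0)))
  cross <- function(r) {
    tr <- integrate_metapop(c(0.01, 0.01), lk,
                            model_params(r = r, s = 0), horizon = 80)
    idx <- which(tr$aggregate >= 0.95 * 2)[1]
    # linear interpolation within the unit interval
    a <- tr$aggregate
    (idx - 2) + (0.95 * 2 - a[idx - 1]) / (a[idx] - a[idx - 1])
  }
  expect_equal(cross(0.15) / cross(0.2), 0.2 / 0.15, tolerance = 0.005)
  expect_equal(cross(0.25) / cross(0.2), 0.2 / 0.25, tolerance = 0.005)
})
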