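test_that("recovery time is the first checkpoint at 95% of baseline", {
  # shallow removal: already above threshold at t = 0
  traj <- structure(list(times = 0:5, aggregate = c(0.97, 0.98, 0.99, 1, 1, 1) * 2,
                         X = NULL, disturbed_mask = c(TRUE, FALSE)),
                    class = "metapop_trajectory")
  rr <- recovery_time(traj, initial_aggregate = 2)
  expect_equal(rr$recovery_time, 0L)
  expect_false(rr$censored)
  expect_equal(rr$n_disturbed, 1)

  # two isolated reefs, both 99% removed: aggregate crossing at the
  # closed-form logistic time 37.70, hence checkpoint 38
  lk <- build_links(reef_nodes(c(0, 10), c(0, 0)))
  p <- model_params(r = 0.2, s = 0)
  tr <- integrate_metapop(c(0.01, 0.01), lk, p, horizon = 60)
  rr <- recovery_time(tr, initial_aggregate = 2)
  expect_equal(rr$recovery_time, 38L)
  expect_equal(rr$recovery_time, as.integer(ceiling(logistic_time(0.95))))

  # a 10-step horizon cannot contain the 37.7-step recovery
  tr10 <- integrate_metapop(c(0.01, 0.01), lk, p, horizon = 10)
  expect_true(recovery_time(tr10, initial_aggregate = 2)$censored)
})

test_that("replicates are bit-identical under the same seed", {
  nd <- small_strip(25, seed = 4)
  lk <- build_links(nd)
  p <- model_params(s = 0.5)
  a <- run_replicate(nd, lk, p, alpha = 100, seed = 313)
  b <- run_replicate(nd, lk, p, alpha = 100, seed = 313)
  expect_identical(a, b)
})

test_that("at s = 0 recovery is exactly invariant to the link subset", {
  nd <- small_strip(25, seed = 4)
  lk <- build_links(nd)
  p <- model_params(s = 0)
  for (seed in c(1, 2, 3)) {
    rts <- vapply(c(20, 200, nrow(lk)), function(alpha)
      run_replicate(nd, lk, p, alpha = alpha, seed = seed)$recovery_time, 1L)
    expect_equal(rts[2], rts[1])
    expect_equal(rts[3], rts[1])
  }
})

test_that("link weights are irrelevant at s = 0", {
  nd <- small_strip(25, seed = 8)
  lk <- build_links(nd)
  uniform <- reefresilience:::scenario_links(lk, nd, "uniform")
  steep <- reefresilience:::scenario_links(lk, nd, "steep")
  p <- model_params(s = 0)
  for (seed in 11:13) {
    base <- run_replicate(nd, lk, p, seed = seed)$recovery_time
    expect_identical(run_replicate(nd, uniform, p, seed = seed)$recovery_time, base)
    expect_identical(run_replicate(nd, steep, p, seed = seed)$recovery_time, base)
  }
})

test_that("a milder disturbance never slows recovery", {
  nd <- small_strip(25, seed = 6)
  lk <- build_links(nd)
  p <- model_params(s = 0)
  for (seed in 21:26) {
    deep <- run_replicate(nd, lk, p, removal_fraction = 0.99, seed = seed)
    mild <- run_replicate(nd, lk, p, removal_fraction = 0.5, seed = seed)
    expect_equal(mild$n_disturbed, deep$n_disturbed)  # same event
    expect_lte(mild$recovery_time, deep$recovery_time)
  }
})

test_that("grid sweeps have the requested shape and rerun bit-identically", {
  nd <- small_strip(20, seed = 10)
  lk <- build_links(nd)
  surf <- run_grid(nd, lk, s_values = c(0, 0.5, 1), alpha_values = c(50, nrow(lk)),
                   n_reps = 10, base_seed = 99)
  expect_s3_class(surf, "resilience_surface")
  expect_equal(dim(surf$mean), c(3, 2))
  expect_true(all(surf$n + surf$n_censored == 10))
  surf2 <- run_grid(nd, lk, s_values = c(0, 0.5, 1),
                    alpha_values = c(50, nrow(lk)), n_reps = 10, base_seed = 99)
  expect_identical(surf, surf2)

  # default grids: 11 quality levels x 10 link counts
  surf3 <- run_grid(nd, lk, n_reps = 1,
                    alpha_values = round(seq(10, nrow(lk), length.out = 10)))
  expect_equal(dim(surf3$mean), c(11, 10))

  df <- as.data.frame(surf)
  expect_equal(nrow(df), 6)
  f <- withr::local_tempfile()
  write_surface(surf, f)
  back <- read_surface(f)
  expect_equal(back$mean, surf$mean, tolerance = 1e-6)
})

test_that("the scenario suite emits the expected table and gradient guards", {
  nd <- small_strip(20, seed = 11)
  lk <- build_links(nd)
  tab <- run_scenarios(nd, lk, n_reps = 3, base_seed = 5)
  expect_equal(nrow(tab), 16)  # 8 scenarios x 2 quality levels
  expect_setequal(unique(tab$s), c(0, 1))
  expect_true(all(tab$n + tab$n_censored == 3))

  r_n <- reefresilience:::scenario_growth("north", nd, 0.05)
  r_s <- reefresilience:::scenario_growth("south", nd, 0.05)
  expect_equal(mean(r_n), 0.2, tolerance = 1e-12)
  expect_equal(max(abs(r_n - 0.2)), 0.05)
  expect_equal(r_n - 0.2, -(r_s - 0.2))
  expect_gt(stats::cor(r_n, nd$y), 0.99)
  sym <- reef_nodes(c(0, 0.05, 0.1, 0.15), c(-0.1, -0.05, 0.05, 0.1))
  expect_error(reefresilience:::scenario_growth("north", sym, 0.3),
               "gradient too steep")
})

test_that("trajectory summaries split disturbed and undisturbed groups", {
  nd <- small_strip(20, seed = 12)
  lk <- build_links(nd)
  p <- model_params(s = 0)
  r1 <- run_replicate(nd, lk, p, seed = 3, return_trajectory = TRUE)
  tr1 <- attr(r1, "trajectory")
  one <- summarize_trajectories(list(tr1))
  expect_true(all(one$sd == 0))
  expect_true(all(one$n == 1))
  # undisturbed group stays flat at carrying capacity when s = 0
  und <- one[one$group == "undisturbed", ]
  expect_equal(und$mean, rep(1, nrow(und)))
  expect_true(all(one$mean >= 0 & one$mean <= 1 + 1e-9))

  r2 <- run_replicate(nd, lk, p, seed = 4, return_trajectory = TRUE)
  two <- summarize_trajectories(list(tr1, attr(r2, "trajectory")))
  expect_true(all(two$n == 2))
  dist <- two[two$group == "disturbed", ]
  expect_lt(dist$mean[1], 0.05)
  expect_true(all(diff(dist$mean) >= -1e-9))
})

test_that("trajectory CSV export round-trips the aggregate series", {
  nd <- small_strip(10, seed = 14)
  lk <- build_links(nd)
  r <- run_replicate(nd, lk, model_params(s = 0), seed = 9,
                     return_trajectory = TRUE)
  tr <- attr(r, "trajectory")
  f <- withr::local_tempfile()
  write_trajectory(tr, f)
  df <- utils::read.table(f, sep = ",", header = TRUE, comment.char = "#")
  agg <- df$biomass[df$node_id == 0]
  expect_equal(agg, tr$aggregate, tolerance = 1e-9)
  expect_equal(sum(df$disturbed[df$node_id > 0 & df$time == 0]),
               sum(tr$disturbed_mask))
})
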