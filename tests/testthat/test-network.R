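test_that("node files parse across dialects and re-index contiguously", {
  f <- withr::local_tempfile()
  writeLines(c("0 0", "1 0", "0 1"), f)
  nd <- read_reef_nodes(f)
  expect_s3_class(nd, "reef_nodes")
  expect_equal(nrow(nd), 3)
  expect_equal(nd$id, 1:3)

  # header + comma + leading id column, ids deliberately non-contiguous
  writeLines(c("id,x,y", "7,0,0", "9,1,0", "12,0,1"), f)
  nd2 <- read_reef_nodes(f)
  expect_equal(nd2$id, 1:3)
  expect_equal(nd2$x, c(0, 1, 0))

  writeLines(character(0), f)
  expect_error(read_reef_nodes(f), "no nodes")
  writeLines("0 0", f)
  expect_error(read_reef_nodes(f), "at least 2")
  writeLines(c("0 zero", "1 0"), f)
  expect_error(read_reef_nodes(f), "non-numeric")
  expect_error(read_reef_nodes(file.path(tempdir(), "absent.txt")), "not found")
})

test_that("pairwise distances match an independent element-wise loop", {
  nd <- reef_nodes(c(0, 3), c(0, 4))
  expect_equal(node_distances(nd)[1, 2], 5)

  set.seed(11)
  nd <- reef_nodes(runif(10), runif(10))
  d <- node_distances(nd)
  expect_equal(diag(d), rep(0, 10))
  for (i in 1:10) for (j in 1:10)
    expect_equal(d[i, j],
                 sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2))
})

test_that("link rule keeps exactly the super-threshold pairs, symmetrically", {
  # w(0.1) = exp(-4.25): retained; w(0.25): below 0.01, dropped
  lk <- build_links(toy_pair())
  expect_equal(nrow(lk), 2)
  expect_equal(lk$weight, rep(exp(-3.4 * 0.1 - 3.91), 2))
  far <- build_links(reef_nodes(c(0, 0.25), c(0, 0)))
  expect_equal(nrow(far), 0)
  expect_lt(exp(-3.4 * 0.25 - 3.91), 0.01)

  expect_equal(link_cutoff_distance(), (log(100) - 3.91) / 3.4)
  expect_equal(link_cutoff_distance(), 0.2044617, tolerance = 1e-6)
  # just inside / just outside the cutoff distance
  eps <- 1e-9
  expect_equal(nrow(build_links(reef_nodes(c(0, 0.2044617 - 1e-4), c(0, 0)))), 2)
  expect_equal(nrow(build_links(reef_nodes(c(0, 0.2044617 + 1e-4), c(0, 0)))), 0)

  # threshold soundness + weight symmetry on a random dense set
  nd <- small_strip(40, seed = 3)
  lk <- build_links(nd)
  expect_no_links_beyond_threshold(nd, lk)
  key <- paste(lk$from, lk$to)
  rev <- paste(lk$to, lk$from)
  expect_setequal(key, rev)
  expect_equal(lk$weight, lk$weight[match(key, rev)])
  expect_true(all(lk$from != lk$to))

  # base weight strictly decreasing in distance
  d <- seq(0, 0.2, by = 0.01)
  w <- exp(-3.4 * d - 3.91)
  expect_true(all(diff(w) < 0))

  # duplicate coordinates: distinct nodes at d = 0 carry the maximal weight
  dup <- build_links(reef_nodes(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(nrow(dup), 2)
  expect_equal(dup$weight, rep(exp(-3.91), 2))
})

test_that("link files round-trip and diffs pinpoint discrepancies", {
  nd <- small_strip(20, seed = 5)
  lk <- build_links(nd)
  f <- withr::local_tempfile()
  write_reef_links(lk, f)
  back <- read_reef_links(f, n_nodes = nrow(nd))
  diff <- compare_links(lk, back)
  expect_equal(nrow(diff$only_in_built), 0)
  expect_equal(nrow(diff$only_in_loaded), 0)
  expect_lt(diff$max_weight_diff, 1e-6)

  # drop one link: diff of size one naming the pair
  dropped <- back[-4, ]
  attr(dropped, "n_nodes") <- attr(back, "n_nodes")
  class(dropped) <- class(back)
  diff2 <- compare_links(lk, dropped)
  expect_equal(nrow(diff2$only_in_built), 1)
  expect_equal(diff2$only_in_built$from, back$from[4])
  expect_equal(diff2$only_in_built$to, back$to[4])

  # perturb one weight: discrepancy surfaces in the max weight diff
  pert <- back
  pert$weight[7] <- pert$weight[7] + 0.005
  expect_gt(compare_links(lk, pert)$max_weight_diff, 0.004)

  writeLines(c("1 2", "2 x"), f)
  expect_error(read_reef_links(f), "malformed")
  writeLines(c("1 99 0.5"), f)
  expect_error(read_reef_links(f, n_nodes = 10), "outside node range")
})

test_that("link subsampling is exact, seeded, and unbiased", {
  nd <- small_strip(25, seed = 7)
  lk <- build_links(nd)
  m <- nrow(lk)

  full <- sample_links(lk, m, seed = 1)
  expect_equal(nrow(full), m)

  sub <- sample_links(lk, 50, seed = 42)
  expect_equal(nrow(sub), 50)
  expect_equal(sum(attr(sub, "mask")), 50)
  expect_true(all(paste(sub$from, sub$to) %in% paste(lk$from, lk$to)))
  expect_identical(sample_links(lk, 50, seed = 42)$from, sub$from)

  # complementary subsets partition the parent set
  comp <- lk[!attr(sub, "mask"), ]
  expect_setequal(c(paste(sub$from, sub$to), paste(comp$from, comp$to)),
                  paste(lk$from, lk$to))

  expect_error(sample_links(lk, 0), "alpha")
  expect_error(sample_links(lk, m + 1), "alpha")

  # inclusion frequency at alpha = m/2 is 1/2 for every link
  half <- floor(m / 2)
  n_draw <- 2000
  counts <- integer(m)
  set.seed(99)
  for (i in seq_len(n_draw))
    counts <- counts + attr(sample_links(lk, half), "mask")
  p <- half / m
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(counts / n_draw - p) < 4 * se))
})

test_that("synthetic strips are reproducible and match the target density", {
  a <- synthesize_reef_nodes(seed = 7)
  b <- synthesize_reef_nodes(seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 114)

  # two nodes in a tiny patch are forced within the cutoff distance
  tiny <- synthesize_reef_nodes(2, extent = c(0.1, 0.1), seed = 1)
  expect_equal(nrow(build_links(tiny)), 2)

  # default 114-node strip lands near the reference link count
  counts <- vapply(1:5, function(s)
    nrow(build_links(synthesize_reef_nodes(seed = s))), 1L)
  expect_true(all(abs(counts - 3904) / 3904 < 0.25))

  # degree targeting rescales the strip
  nd <- synthesize_reef_nodes(60, seed = 2, target_out_degree = 10)
  deg <- nrow(build_links(nd)) / 60
  expect_lt(abs(deg - 10), 2)
  expect_warning(
    synthesize_reef_nodes(10, extent = c(1, 1), seed = 1,
                          target_out_degree = 50),
    "incompatible")
})
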