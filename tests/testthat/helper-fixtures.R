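# Two reefs one tenth of a unit apart: each has exactly one out-link.
toy_pair <- function() reef_nodes(c(0, 0.1), c(0, 0))

# Three mutually equidistant reefs (side 0.1 < link cutoff).
toy_triangle <- function() reef_nodes(c(0, 0.1, 0.05), c(0, 0, 0.05 * sqrt(3)))

# Small dense strip for property tests (same spatial density regime as the
# default 114-node strip, scaled down for speed).
small_strip <- function(n = 30, seed = 1)
  synthesize_reef_nodes(n, extent = c(1.45, 1.45 / 15) * n / 114, seed = seed)

# Closed-form logistic solution, biomass scaled to carrying capacity.
logistic_closed <- function(t, x0 = 0.01, r = 0.2)
  x0 * exp(r * t) / (1 + x0 * (exp(r * t) - 1))

# Closed-form time for the logistic to rise from x0 to x.
logistic_time <- function(x, x0 = 0.01, r = 0.2)
  (1 / r) * log(x * (1 - x0) / (x0 * (1 - x)))

expect_no_links_beyond_threshold <- function(nodes, links) {
  d <- node_distances(nodes)
  w <- exp(-attr(links, "decay_slope") * d - attr(links, "decay_intercept"))
  keep <- w > attr(links, "threshold")
  diag(keep) <- FALSE
  stored <- matrix(FALSE, nrow(d), nrow(d))
  stored[cbind(links$from, links$to)] <- TRUE
  expect_identical(stored, keep)
}
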