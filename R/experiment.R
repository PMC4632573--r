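#' Recovery time (Pimm resilience) of a trajectory
#'
#' The recovery time is the first unit-time checkpoint at which the aggregate
#' biomass of the entire metapopulation reaches a fraction `threshold` of its
#' pre-disturbance value; 0 if the post-disturbance state already satisfies
#' it, censored (`NA`) if the horizon is exhausted first.
#'
#' @param trajectory a `metapop_trajectory` whose first checkpoint is the
#'   immediate post-disturbance state.
#' @param initial_aggregate pre-disturbance aggregate biomass.
#' @param threshold recovery fraction (default 0.95).
#' @param seed optional seed to record for provenance.
#' @return An object of class `recovery_result`: list with `recovery_time`
#'   (integer checkpoint or `NA` when censored), `censored`, `n_disturbed`,
#'   `initial_aggregate`, `post_disturbance_aggregate`, `seed`.
#' @export
recovery_time <- function(trajectory, initial_aggregate, threshold = 0.95,
                          seed = NA_integer_) {
  agg <- trajectory$aggregate
  if (length(agg) == 0L) stop("empty trajectory")
  hit <- which(agg >= threshold * initial_aggregate)
  rt <- if (length(hit)) trajectory$times[hit[1]] else NA_integer_
  mask <- trajectory$disturbed_mask
  structure(list(recovery_time = as.integer(rt), censored = is.na(rt),
                 n_disturbed = if (is.null(mask)) NA_integer_ else sum(mask),
                 initial_aggregate = initial_aggregate,
                 post_disturbance_aggregate = agg[1],
                 seed = seed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery_result: %s (disturbed %s nodes, aggregate %.4g -> %.4g)\n",
              if (x$censored) "censored" else paste(x$recovery_time, "time steps"),
              x$n_disturbed, x$initial_aggregate, x$post_disturbance_aggregate))
  invisible(x)
}

# Fast single-replicate pipeline on prebuilt edge vectors. `ea_full` is the
# full link set's columns; idx selects the sampled subset.
replicate_core <- function(nodes, from, to, w, n, r_vec, s, mode_i, dt,
                           relax_dt, t_max, tol, radius, removal_fraction,
                           require_hit, threshold, w_out_full = NULL,
                           eq_state = NULL, record = FALSE,
                           max_redraws = 10000L) {
  w_out <- numeric(n); w_in <- numeric(n)
  if (length(from)) {
    tw <- rowsum(w, from); w_out[as.integer(rownames(tw)) + 1L] <- tw
    ti <- rowsum(w, to);   w_in[as.integer(rownames(ti)) + 1L] <- ti
  }
  escale <- if (mode_i == 2L) as.numeric(w_out > 0)
            else if (is.null(w_out_full)) as.numeric(w_out > 0)
            else ifelse(w_out_full > 0, w_out / w_out_full, 0)
  if (is.null(eq_state)) {
    if (s == 0 || length(from) == 0L) {
      eq_state <- rep(1, n)
    } else {
      rl <- cpp_relax(rep(1, n), from, to, w, w_out, w_in, escale, r_vec, s,
                      mode_i, relax_dt, as.integer(t_max), tol)
      if (rl$status != 0L) stop("non-finite state during relaxation")
      eq_state <- rl$X
    }
  }
  init_agg <- sum(eq_state)
  bbx <- range(nodes$x); bby <- range(nodes$y)
  draws <- 0L
  repeat {
    draws <- draws + 1L
    cx <- runif(1, bbx[1], bbx[2]); cy <- runif(1, bby[1], bby[2])
    mask <- (nodes$x - cx)^2 + (nodes$y - cy)^2 <= radius^2
    if (!require_hit || any(mask)) break
    if (draws >= max_redraws)
      stop("no disturbance centre hit any node after ", max_redraws, " draws")
  }
  state <- eq_state
  state[mask] <- state[mask] * (1 - removal_fraction)
  res <- cpp_integrate(state, from, to, w, w_out, w_in, escale, r_vec, s,
                       mode_i, dt, as.integer(t_max), record, threshold,
                       init_agg)
  if (res$status != 0L)
    stop("non-finite state during integration")
  list(t_rec = res$t_rec, mask = mask, init_agg = init_agg,
       post_agg = sum(state), X = res$X, agg = res$agg,
       eq_state = eq_state, event = c(cx, cy), draws = draws)
}

#' Run one seeded disturbance-recovery replicate
#'
#' Full pipeline: draw a random subset of `alpha` links, relax the
#' undisturbed system to equilibrium, sample a disturbance, apply it, and
#' integrate until the aggregate recovers (or the horizon is exhausted).
#' Fully reproducible from `seed` plus the configuration.
#'
#' @param nodes a [reef_nodes] object.
#' @param links the full `reef_links` set.
#' @param params a [model_params] object.
#' @param alpha number of directed links to retain (`NULL` = all).
#' @param radius,removal_fraction,require_hit disturbance settings
#'   (see [sample_event]).
#' @param seed integer seed for this replicate.
#' @param threshold recovery fraction (default 0.95).
#' @param return_trajectory also return the recorded trajectory.
#' @param equilibrium optional precomputed equilibrium state (used by
#'   [run_grid]/[run_scenarios] to avoid re-relaxing when the link subset is
#'   the full set and hence identical across replicates).
#' @return A `recovery_result`; when `return_trajectory = TRUE`, attribute
#'   `trajectory` holds the `metapop_trajectory` up to recovery.
#' @export
run_replicate <- function(nodes, links, params, alpha = NULL, radius = 0.4,
                          removal_fraction = 0.99, require_hit = TRUE,
                          seed = 1L, threshold = 0.95,
                          return_trajectory = FALSE, equilibrium = NULL) {
  stopifnot(inherits(nodes, "reef_nodes"), inherits(links, "reef_links"))
  n <- attr(links, "n_nodes")
  if (n != nrow(nodes)) stop("links and nodes disagree on node count")
  # Independent RNG phases for link sampling and event placement: the event
  # draw is identical across alpha values under the same seed, so recovery
  # at s = 0 is exactly invariant to the subset size.
  set.seed(seed)
  phase <- sample.int(2147483646L, 2)
  m <- nrow(links)
  w_out_full <- attr(links, "w_out_full")
  if (!is.null(alpha) && alpha < m) {
    set.seed(phase[1])
    idx <- sample.int(m, alpha)
    if (is.null(w_out_full)) {
      w_out_full <- numeric(n)
      tw <- rowsum(links$weight, links$from)
      w_out_full[as.integer(rownames(tw))] <- tw
    }
    from <- as.integer(links$from[idx]) - 1L
    to <- as.integer(links$to[idx]) - 1L
    w <- links$weight[idx]
  } else {
    from <- as.integer(links$from) - 1L
    to <- as.integer(links$to) - 1L
    w <- links$weight
  }
  set.seed(phase[2])
  core <- replicate_core(nodes, from, to, w, n, expand_r(params$r, n),
                         params$s, mode_code(params$migration_mode),
                         params$dt, params$relax_dt, params$t_max,
                         params$burn_in_tol, radius, removal_fraction,
                         require_hit, threshold, w_out_full = w_out_full,
                         eq_state = equilibrium,
                         record = return_trajectory)
  rt <- if (core$t_rec >= 0L) core$t_rec else NA_integer_
  out <- structure(list(recovery_time = as.integer(rt), censored = is.na(rt),
                        n_disturbed = sum(core$mask),
                        initial_aggregate = core$init_agg,
                        post_disturbance_aggregate = core$post_agg,
                        seed = seed),
                   class = "recovery_result")
  if (return_trajectory) {
    ntimes <- length(core$agg)
    attr(out, "trajectory") <- structure(
      list(times = 0:(ntimes - 1L), X = core$X, aggregate = core$agg,
           disturbed_mask = core$mask),
      class = "metapop_trajectory")
  }
  out
}

# Hierarchical per-replicate seed: cells and replicates are independently
# reproducible. Exact in double precision (< 2^53), reduced below 2^31.
derive_seed <- function(base_seed, cell, rep) {
  as.integer((as.numeric(base_seed) %% 65536 * 1e9 +
                as.numeric(cell) * 2e6 + as.numeric(rep)) %% 2147483629)
}

#' Sweep connection quality against connection quantity
#'
#' Monte-Carlo sweep over a grid of connection quality `s` and connection
#' quantity `alpha`: every cell runs `n_reps` independent replicates, each
#' with its own random link subset and disturbance location, and records the
#' mean and standard deviation of recovery time.
#'
#' @inheritParams run_replicate
#' @param s_values grid of `s` values (default 11 values 0..1).
#' @param alpha_values grid of link counts (default 10 evenly spaced integers
#'   from 200 to the full link count).
#' @param n_reps replicates per cell.
#' @param base_seed integer; replicate seeds are derived hierarchically from
#'   `(base_seed, cell, replicate)` so any cell can be reproduced alone.
#' @param params template [model_params]; `s` is overridden per cell.
#' @return An object of class `resilience_surface`: grids plus matrices
#'   `mean`, `sd`, `n`, `n_censored` (rows = `s`, columns = `alpha`).
#' @export
run_grid <- function(nodes, links, s_values = seq(0, 1, by = 0.1),
                     alpha_values = NULL, n_reps = 100, base_seed = 1L,
                     params = model_params(), radius = 0.4,
                     removal_fraction = 0.99, require_hit = TRUE,
                     threshold = 0.95) {
  stopifnot(inherits(nodes, "reef_nodes"), inherits(links, "reef_links"))
  m <- nrow(links)
  if (is.null(alpha_values)) {
    # 200..3904 on the reference network; scaled proportionally when the
    # link set is smaller
    lo <- max(1, round(m * 200 / 3904))
    alpha_values <- unique(round(seq(min(lo, m), m, length.out = 10)))
  }
  alpha_values <- as.integer(alpha_values)
  if (is.unsorted(s_values, strictly = TRUE) ||
      is.unsorted(alpha_values, strictly = TRUE))
    stop("s_values and alpha_values must be strictly increasing")
  if (any(alpha_values < 1L) || any(alpha_values > m))
    stop("alpha_values must lie in 1..", m)
  n <- attr(links, "n_nodes")
  r_vec <- expand_r(params$r, n)
  mode_i <- mode_code(params$migration_mode)
  from_all <- as.integer(links$from) - 1L
  to_all <- as.integer(links$to) - 1L
  w_all <- links$weight
  w_out_full <- numeric(n)
  tw_full <- rowsum(w_all, from_all)
  w_out_full[as.integer(rownames(tw_full)) + 1L] <- tw_full
  ns <- length(s_values); na <- length(alpha_values)
  mean_m <- sd_m <- matrix(NA_real_, ns, na)
  n_m <- cens_m <- matrix(0L, ns, na)
  cell <- 0L
  for (is in seq_len(ns)) {
    s <- s_values[is]
    for (ia in seq_len(na)) {
      cell <- cell + 1L
      alpha <- alpha_values[ia]
      full_subset <- alpha == m
      eq_cache <- NULL
      rts <- integer(n_reps); cens <- logical(n_reps)
      for (rep in seq_len(n_reps)) {
        set.seed(derive_seed(base_seed, cell, rep))
        phase <- sample.int(2147483646L, 2)
        if (full_subset) {
          from <- from_all; to <- to_all; w <- w_all
        } else {
          set.seed(phase[1])
          idx <- sample.int(m, alpha)
          from <- from_all[idx]; to <- to_all[idx]; w <- w_all[idx]
        }
        set.seed(phase[2])
        core <- replicate_core(nodes, from, to, w, n, r_vec, s, mode_i,
                               params$dt, params$relax_dt, params$t_max,
                               params$burn_in_tol, radius, removal_fraction,
                               require_hit, threshold,
                               w_out_full = if (full_subset) NULL else w_out_full,
                               eq_state = eq_cache)
        if (full_subset) eq_cache <- core$eq_state
        rts[rep] <- core$t_rec
        cens[rep] <- core$t_rec < 0L
      }
      ok <- rts[!cens]
      n_m[is, ia] <- length(ok)
      cens_m[is, ia] <- sum(cens)
      if (length(ok)) {
        mean_m[is, ia] <- mean(ok)
        sd_m[is, ia] <- if (length(ok) > 1L) stats::sd(ok) else 0
      }
    }
  }
  structure(list(s = s_values, alpha = alpha_values, mean = mean_m,
                 sd = sd_m, n = n_m, n_censored = cens_m, n_reps = n_reps,
                 base_seed = base_seed, threshold = threshold),
            class = "resilience_surface")
}

#' @export
print.resilience_surface <- function(x, ...) {
  cat(sprintf("resilience_surface: %d x %d (s x alpha) cells, %d reps each\n",
              length(x$s), length(x$alpha), x$n_reps))
  cat(sprintf("  mean recovery time %.1f .. %.1f; %d censored replicates total\n",
              min(x$mean, na.rm = TRUE), max(x$mean, na.rm = TRUE),
              sum(x$n_censored)))
  invisible(x)
}

#' @export
as.data.frame.resilience_surface <- function(x, ...) {
  g <- expand.grid(s = x$s, alpha = x$alpha)
  data.frame(s = g$s, alpha = g$alpha, mean = as.vector(x$mean),
             sd = as.vector(x$sd), n = as.vector(x$n),
             n_censored = as.vector(x$n_censored))
}

#' Write / read a resilience surface as long-format CSV
#'
#' Columns `s, alpha, mean, sd, n, n_censored`.
#'
#' @param surface a `resilience_surface`.
#' @param path file path.
#' @export
write_surface <- function(surface, path) {
  df <- as.data.frame(surface)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# resilience surface: base_seed %s, n_reps %d, threshold %g",
                     surface$base_seed, surface$n_reps, surface$threshold), con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(sprintf, c(list("%g,%d,%g,%g,%d,%d"), df)), con)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#")
  s <- sort(unique(df$s)); alpha <- sort(unique(df$alpha))
  df <- df[order(match(df$alpha, alpha), match(df$s, s)), ]
  shape <- function(col) matrix(col, nrow = length(s))
  structure(list(s = s, alpha = as.integer(alpha), mean = shape(df$mean),
                 sd = shape(df$sd), n = shape(df$n),
                 n_censored = shape(df$n_censored),
                 n_reps = max(df$n + df$n_censored), base_seed = NA,
                 threshold = NA),
            class = "resilience_surface")
}

#' The standard sensitivity-scenario suite
#'
#' Eight scenarios probing growth rate, disturbance severity, the spatial
#' reach of migration, and latitudinal growth gradients, each run on the full
#' link set at both `s = 1` and `s = 0` by [run_scenarios].
#'
#' @param gradient_max maximum absolute deviation of the per-node growth
#'   rate from 0.2 in the latitude-gradient scenarios (default 0.05, giving
#'   rates in `[0.15, 0.25]` whatever the coordinate span).
#' @return A list of scenario specifications (name, growth specification,
#'   removal fraction, link-rule override).
#' @export
scenario_suite <- function(gradient_max = 0.05) {
  spec <- function(name, r = 0.2, removal = 0.99, override = "none")
    list(name = name, r = r, removal_fraction = removal,
         link_override = override, gradient_max = gradient_max)
  list(
    spec("base case"),
    spec("r = 0.25", r = 0.25),
    spec("r = 0.15", r = 0.15),
    spec("disturbance = 50%", removal = 0.5),
    spec("no spatial effect on migration", override = "uniform"),
    spec("twice spatial effect on migration", override = "steep"),
    spec("r northerly increase", r = "north"),
    spec("r southerly increase", r = "south")
  )
}

scenario_growth <- function(r_spec, nodes, gradient_max) {
  if (is.numeric(r_spec)) return(r_spec)
  dev <- nodes$y - mean(nodes$y)
  span <- max(abs(dev))
  if (span == 0) return(0.2)
  g <- gradient_max / span
  r <- switch(r_spec,
              north = 0.2 + g * dev,
              south = 0.2 - g * dev,
              stop("unknown growth specification: ", r_spec))
  if (any(r <= 0)) stop("latitude gradient too steep: non-positive growth rate")
  r
}

# Link-rule overrides, following the scenario definitions: "uniform" removes
# any spatial effect of migration (every ordered pair connected with weight
# 1, so there is no penalty for migration between the strip's extremes);
# "steep" doubles the decay slope and re-applies the retention threshold,
# halving the distance over which sub-populations exchange migrants.
scenario_links <- function(links, nodes, override) {
  if (override == "none") return(links)
  n <- attr(links, "n_nodes")
  if (override == "uniform") {
    g <- expand.grid(from = seq_len(n), to = seq_len(n))
    g <- g[g$from != g$to, ]
    out <- data.frame(from = g$from, to = g$to, weight = 1)
    out <- out[order(out$from, out$to), ]
    rownames(out) <- NULL
    structure(out, class = c("reef_links", "data.frame"), n_nodes = n,
              decay_slope = NA_real_, decay_intercept = NA_real_,
              threshold = attr(links, "threshold"))
  } else if (override == "steep") {
    b <- attr(links, "decay_intercept")
    if (is.na(b)) b <- 3.91
    thr <- attr(links, "threshold")
    if (is.na(thr)) thr <- 0.01
    build_links(nodes, decay_slope = 6.8, decay_intercept = b,
                threshold = thr)
  } else stop("unknown link override: ", override)
}

#' Run the sensitivity-scenario suite
#'
#' Each scenario is run on the full link set for each value of `s` in
#' `s_levels`, with the undisturbed equilibrium computed once per
#' scenario-by-s combination (the link subset is the full set in every
#' replicate, so the equilibrium is shared).
#'
#' @inheritParams run_grid
#' @param suite list of scenario specifications (see [scenario_suite]).
#' @param s_levels connection-quality levels (default `c(1, 0)`).
#' @return A `data.frame` with one row per scenario-by-s: `scenario`, `s`,
#'   `mean`, `sd`, `n`, `n_censored`.
#' @export
run_scenarios <- function(nodes, links, suite = scenario_suite(),
                          s_levels = c(1, 0), n_reps = 100, base_seed = 1L,
                          params = model_params(), radius = 0.4,
                          require_hit = TRUE, threshold = 0.95) {
  rows <- list()
  cell <- 0L
  n <- attr(links, "n_nodes")
  mode_i <- mode_code(params$migration_mode)
  for (sc in suite) {
    r_vec <- expand_r(scenario_growth(sc$r, nodes, sc$gradient_max), n)
    lk <- scenario_links(links, nodes, sc$link_override)
    from <- as.integer(lk$from) - 1L
    to <- as.integer(lk$to) - 1L
    w <- lk$weight
    for (s in s_levels) {
      cell <- cell + 1L
      eq_cache <- NULL
      rts <- integer(n_reps); cens <- logical(n_reps)
      for (rep in seq_len(n_reps)) {
        set.seed(derive_seed(base_seed, cell, rep))
        phase <- sample.int(2147483646L, 2)
        set.seed(phase[2])
        core <- replicate_core(nodes, from, to, w, n, r_vec, s, mode_i,
                               params$dt, params$relax_dt, params$t_max,
                               params$burn_in_tol, radius,
                               sc$removal_fraction, require_hit, threshold,
                               eq_state = eq_cache)
        eq_cache <- core$eq_state
        rts[rep] <- core$t_rec
        cens[rep] <- core$t_rec < 0L
      }
      ok <- rts[!cens]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, s = s,
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
        n = length(ok), n_censored = sum(cens))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group trajectories into disturbed / undisturbed mean paths
#'
#' For each replicate trajectory, the per-checkpoint mean biomass of its
#' disturbed and of its undisturbed sub-populations is computed; across
#' replicates these group paths are summarized as mean and standard
#' deviation per checkpoint (trajectories are truncated to the shortest
#' common checkpoint grid).
#'
#' @param trajectories list of `metapop_trajectory` objects.
#' @param masks optional list of logical disturbance masks (defaults to each
#'   trajectory's own `disturbed_mask`).
#' @return A `data.frame` with columns `time`, `group` ("disturbed" /
#'   "undisturbed"), `mean`, `sd`, `n`.
#' @export
summarize_trajectories <- function(trajectories, masks = NULL) {
  if (length(trajectories) == 0L) stop("need at least one trajectory")
  if (is.null(masks))
    masks <- lapply(trajectories, function(tr) tr$disturbed_mask)
  tmax <- min(vapply(trajectories, function(tr) length(tr$times), 1L))
  out <- list()
  for (group in c("disturbed", "undisturbed")) {
    paths <- mapply(function(tr, mk) {
      sel <- if (group == "disturbed") mk else !mk
      if (!any(sel)) return(NULL)
      rowMeans(tr$X[seq_len(tmax), sel, drop = FALSE])
    }, trajectories, masks, SIMPLIFY = FALSE)
    paths <- paths[!vapply(paths, is.null, TRUE)]
    if (length(paths) == 0L) {
      warning("no trajectory has any ", group, " node; empty series")
      next
    }
    pm <- do.call(cbind, paths)
    out[[group]] <- data.frame(
      time = trajectories[[1]]$times[seq_len(tmax)], group = group,
      mean = rowMeans(pm),
      sd = if (ncol(pm) > 1L) apply(pm, 1, stats::sd) else rep(0, nrow(pm)),
      n = ncol(pm))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
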