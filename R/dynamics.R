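#' Model parameters for the metapopulation dynamics
#'
#' Each sub-population grows logistically (biomass scaled to carrying
#' capacity) and exports a fraction of its production into the dispersal
#' network; `s` scales every migration flow as the survivorship of migrants.
#' Three closures of the immigration term are provided because the printed
#' form of the model does not conserve migrants (see the methods vignette):
#'
#' * `"conservative"` (default): each source emits `s r X_j` scaled by the
#'   retained fraction of its full-network out-weight (removing a corridor
#'   removes the flow that used it), split over its selected out-links in
#'   proportion to their base weights; total immigration equals total
#'   emigration at every instant.
#' * `"pool"`: all emigrant flux enters a common pool which is allocated to
#'   destinations in proportion to their weighted in-flow `sum_j w_ji X_j`;
#'   also mass-conserving, but allocation is global rather than per-source.
#' * `"literal"`: the printed form `k_i * X_tilde` with
#'   `k_i = sum_j L_ji X_j / sum_j L_ji` and `X_tilde = r * sum_j X_j`;
#'   not mass-conserving (it diverges on any connected network with `s > 0`)
#'   and retained for demonstration only.
#'
#' @param r per-unit-time logistic growth rate; scalar or per-node vector
#'   (default 0.2).
#' @param s connection quality (migrant survivorship) in `[0, 1]`.
#' @param migration_mode one of `"conservative"`, `"pool"`, `"literal"`.
#' @param dt integrator step in time units (default 0.05; internally rounded
#'   to the nearest exact divisor of the unit checkpoint interval).
#' @param t_max integration horizon in time units (default 500).
#' @param burn_in_tol equilibrium residual tolerance `max|dX/dt|` for the
#'   pre-disturbance relaxation (default 1e-9).
#' @param relax_dt step used only during burn-in relaxation (default 0.25):
#'   fixed points of the RK4 map coincide with those of the ODE, so a
#'   coarser burn-in step changes the approach path but not the equilibrium.
#' @return An object of class `model_params`.
#' @export
model_params <- function(r = 0.2, s = 1, migration_mode = c("conservative",
                                                            "pool", "literal"),
                         dt = 0.05, t_max = 500, burn_in_tol = 1e-9,
                         relax_dt = 0.25) {
  migration_mode <- match.arg(migration_mode)
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  if (!is.finite(s) || s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  if (dt > 0.5) stop("dt must be at most 0.5 (stability guard)")
  structure(list(r = r, s = s, migration_mode = migration_mode, dt = dt,
                 t_max = t_max, burn_in_tol = burn_in_tol,
                 relax_dt = relax_dt),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: r = %s, s = %g, mode = %s, dt = %g, t_max = %g\n",
              if (length(x$r) == 1L) format(x$r) else
                sprintf("[%.3g..%.3g]", min(x$r), max(x$r)),
              x$s, x$migration_mode, x$dt, x$t_max))
  invisible(x)
}

mode_code <- function(mode) {
  match(mode, c("conservative", "pool", "literal")) - 1L
}

# Precompute the edge arrays the C++ core consumes: 0-based endpoints,
# per-source selected out-weight totals, per-destination in-weight totals,
# and the per-source emigration scale. When `links` is a subset drawn by
# sample_links() the parent's out-weight totals (attribute "w_out_full")
# scale emigration by the retained fraction of each node's dispersal
# corridors; a full link set has scale 1 wherever a node has out-links.
edge_arrays <- function(links, n, mode = "conservative") {
  from <- as.integer(links$from) - 1L
  to <- as.integer(links$to) - 1L
  w <- as.numeric(links$weight)
  w_out <- numeric(n); w_in <- numeric(n)
  if (length(from)) {
    tw <- rowsum(w, from)
    w_out[as.integer(rownames(tw)) + 1L] <- tw
    ti <- rowsum(w, to)
    w_in[as.integer(rownames(ti)) + 1L] <- ti
  }
  escale <- emigration_scale(w_out, attr(links, "w_out_full"), mode)
  list(from = from, to = to, w = w, w_out = w_out, w_in = w_in,
       escale = escale, n = n)
}

emigration_scale <- function(w_out, w_out_full, mode) {
  if (mode == "literal") return(as.numeric(w_out > 0))
  if (is.null(w_out_full)) w_out_full <- w_out
  ifelse(w_out_full > 0, w_out / w_out_full, 0)
}

expand_r <- function(r, n) {
  if (length(r) == 1L) rep(r, n)
  else if (length(r) == n) r
  else stop("r must be scalar or one value per node")
}

#' Instantaneous growth and migration fluxes
#'
#' Decomposes the rate of change of each sub-population into logistic growth,
#' emigration and immigration under the selected migration closure. This is
#' the reference R implementation; the integrator uses an equivalent compiled
#' path (their agreement is tested).
#'
#' @param state numeric biomass vector (scaled to carrying capacity).
#' @param links a `reef_links` object (possibly a sampled subset).
#' @param params a [model_params] object.
#' @return A list with per-node `growth`, `emigration`, `immigration`, plus
#'   the literal-mode quantities `k` (distribution weights) and `x_tilde`
#'   (total production scalar; `NA` in other modes).
#' @export
migration_fluxes <- function(state, links, params) {
  n <- attr(links, "n_nodes")
  if (length(state) != n) stop("state length does not match network")
  r <- expand_r(params$r, n)
  s <- params$s
  ea <- edge_arrays(links, n, params$migration_mode)
  growth <- r * state * (1 - state)
  emigration <- s * r * state * ea$escale
  immigration <- numeric(n)
  k <- rep(NA_real_, n); x_tilde <- NA_real_
  if (length(ea$from) && s > 0) {
    from1 <- ea$from + 1L; to1 <- ea$to + 1L
    mode <- params$migration_mode
    if (mode == "conservative") {
      contrib <- emigration[from1] * ea$w / ea$w_out[from1]
      tw <- rowsum(contrib, to1)
      immigration[as.integer(rownames(tw))] <- tw
    } else if (mode == "pool") {
      E <- sum(emigration)
      num <- numeric(n)
      tw <- rowsum(ea$w * state[from1], to1)
      num[as.integer(rownames(tw))] <- tw
      den <- sum(num)
      if (den > 0) immigration <- E * num / den
    } else { # literal: k_i = sum_j L_ji X_j / sum_j L_ji, L = s * w
      num <- numeric(n)
      tw <- rowsum(ea$w * state[from1], to1)
      num[as.integer(rownames(tw))] <- tw
      k <- ifelse(ea$w_in > 0, num / ea$w_in, 0)
      x_tilde <- sum(r * state)
      immigration <- k * x_tilde
    }
  } else if (params$migration_mode == "literal") {
    k <- rep(0, n); x_tilde <- sum(r * state)
    if (s > 0) immigration <- k * x_tilde
  }
  list(growth = growth, emigration = emigration, immigration = immigration,
       k = k, x_tilde = x_tilde)
}

#' Rate of change of the metapopulation state
#'
#' @inheritParams migration_fluxes
#' @return Numeric vector `growth + immigration - emigration` per node.
#' @export
metapop_derivative <- function(state, links, params) {
  fl <- migration_fluxes(state, links, params)
  fl$growth + fl$immigration - fl$emigration
}

#' Integrate the metapopulation dynamics
#'
#' Classical fixed-step 4th-order Runge-Kutta integration of the coupled
#' logistic-migration system, with biomass clipped at zero after each step
#' and the state recorded at unit-time checkpoints.
#'
#' @inheritParams migration_fluxes
#' @param state initial biomass vector (the first checkpoint of the returned
#'   trajectory).
#' @param horizon number of time units to integrate (default `params$t_max`).
#' @param disturbed_mask optional logical vector tagging disturbed nodes;
#'   carried on the trajectory for downstream summaries.
#' @return An object of class `metapop_trajectory`: list with `times`
#'   (0..horizon), `X` (checkpoints x nodes matrix), `aggregate`
#'   (`rowSums(X)`), and `disturbed_mask`.
#' @export
integrate_metapop <- function(state, links, params, horizon = NULL,
                              disturbed_mask = NULL) {
  n <- attr(links, "n_nodes")
  if (length(state) != n) stop("state length does not match network")
  if (is.null(horizon)) horizon <- params$t_max
  horizon <- as.integer(ceiling(horizon))
  ea <- edge_arrays(links, n, params$migration_mode)
  res <- cpp_integrate(as.numeric(state), ea$from, ea$to, ea$w, ea$w_out,
                       ea$w_in, ea$escale, expand_r(params$r, n), params$s,
                       mode_code(params$migration_mode), params$dt,
                       horizon, TRUE, -1.0, 0.0)
  if (res$status != 0L)
    stop("non-finite state during integration (migration_mode = \"",
         params$migration_mode, "\"); the model is unstable for these ",
         "parameters")
  structure(list(times = 0:horizon, X = res$X, aggregate = res$agg,
                 disturbed_mask = disturbed_mask),
            class = "metapop_trajectory")
}

#' @export
print.metapop_trajectory <- function(x, ...) {
  cat(sprintf("metapop_trajectory: %d nodes, %d checkpoints (t = %g..%g), final aggregate %.4g\n",
              ncol(x$X), length(x$times), min(x$times), max(x$times),
              x$aggregate[length(x$aggregate)]))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Long format `time,node_id,biomass,disturbed`; the aggregate series is
#' written alongside with `node_id = 0`.
#'
#' @param trajectory a `metapop_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  n <- ncol(trajectory$X)
  mask <- trajectory$disturbed_mask
  if (is.null(mask)) mask <- rep(FALSE, n)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# trajectory: time,node_id,biomass,disturbed (node_id 0 = aggregate)", con)
  writeLines("time,node_id,biomass,disturbed", con)
  writeLines(sprintf("%g,0,%.10g,0", trajectory$times, trajectory$aggregate), con)
  for (i in seq_len(n))
    writeLines(sprintf("%g,%d,%.10g,%d", trajectory$times, i,
                       trajectory$X[, i], as.integer(mask[i])), con)
  invisible(path)
}

#' Relax the undisturbed system to its equilibrium
#'
#' Integrates from full carrying capacity (`X = 1` everywhere) until the
#' residual `max |dX/dt|` falls below `burn_in_tol`. This relaxed state is
#' the pre-disturbance baseline: with migration active the all-ones state is
#' not stationary, and "recovering 95% of the initial state" presumes a
#' stationary initial state. With `s = 0` the all-ones state is already the
#' fixed point and is returned immediately.
#'
#' @inheritParams migration_fluxes
#' @return A list with `state` (equilibrium biomass vector), `residual`
#'   (final `max|dX/dt|`), `time` (relaxation time used), and `aggregate`.
#' @export
relax_to_equilibrium <- function(links, params) {
  n <- attr(links, "n_nodes")
  ones <- rep(1, n)
  if (params$s == 0 || nrow(links) == 0L) {
    return(list(state = ones, residual = 0, time = 0, aggregate = n))
  }
  ea <- edge_arrays(links, n, params$migration_mode)
  res <- cpp_relax(ones, ea$from, ea$to, ea$w, ea$w_out, ea$w_in, ea$escale,
                   expand_r(params$r, n), params$s,
                   mode_code(params$migration_mode), params$relax_dt,
                   as.integer(params$t_max), params$burn_in_tol)
  if (res$status != 0L)
    stop("non-finite state during relaxation (migration_mode = \"",
         params$migration_mode, "\")")
  if (res$residual >= params$burn_in_tol)
    stop(sprintf(paste0("equilibrium not reached within t_max = %g ",
                        "(residual %.3g >= tolerance %.3g)"),
                 params$t_max, res$residual, params$burn_in_tol))
  list(state = res$X, residual = res$residual, time = res$t,
       aggregate = sum(res$X))
}
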