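# Non-increasing pool-adjacent-violators fit (wraps stats::isoreg, which
# fits non-decreasing).
pava_decreasing <- function(y) {
  -stats::isoreg(seq_along(y), -y)$yf
}

#' Fit an interpolable model to a resilience surface
#'
#' Bilinear interpolation of the per-cell mean recovery times, optionally
#' preceded by an isotone-regression pass that enforces recovery time
#' non-increasing in both connection quality and quantity (alternating
#' row/column projections). Monte-Carlo cell means are noisy; the smoothing
#' restores the monotonicity the underlying response possesses.
#'
#' @param surface a `resilience_surface` (see [run_grid]), or a list with
#'   fields `s`, `alpha` and a `mean` matrix of matching shape.
#' @param smooth apply the monotone smoothing pass (default `FALSE`).
#' @return An object of class `surface_model` with a `z` matrix used for all
#'   queries (smoothed if requested) and the original `z_raw`.
#' @export
fit_surface <- function(surface, smooth = FALSE) {
  z <- surface$mean
  if (anyNA(z)) stop("incomplete grid: surface has undefined cells")
  if (length(surface$s) < 2L || length(surface$alpha) < 2L)
    stop("need at least a 2 x 2 grid")
  z_raw <- z
  if (smooth) {
    for (pass in 1:4) {
      z <- t(apply(z, 1, pava_decreasing))     # along alpha
      z <- apply(z, 2, pava_decreasing)        # along s
    }
  }
  structure(list(s = surface$s, alpha = surface$alpha, z = z, z_raw = z_raw,
                 smooth = smooth),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: %d x %d grid, s in [%g, %g], alpha in [%d, %d]%s\n",
              length(x$s), length(x$alpha), min(x$s), max(x$s),
              min(x$alpha), max(x$alpha),
              if (x$smooth) ", monotone-smoothed" else ""))
  invisible(x)
}

#' Query a fitted surface
#'
#' Bilinear interpolation within the grid's convex hull; exact at grid nodes.
#'
#' @param model a `surface_model`.
#' @param s,alpha query coordinates (vectors recycled to common length).
#' @return Interpolated mean recovery times.
#' @export
predict_surface <- function(model, s, alpha) {
  k <- max(length(s), length(alpha))
  s <- rep_len(as.numeric(s), k); alpha <- rep_len(as.numeric(alpha), k)
  gs <- model$s; ga <- model$alpha
  eps <- 1e-9
  if (any(s < min(gs) - eps | s > max(gs) + eps |
          alpha < min(ga) - eps | alpha > max(ga) + eps))
    stop("query outside the surface grid domain")
  i <- pmin(pmax(findInterval(s, gs), 1L), length(gs) - 1L)
  j <- pmin(pmax(findInterval(alpha, ga), 1L), length(ga) - 1L)
  ts <- (s - gs[i]) / (gs[i + 1] - gs[i])
  ta <- (alpha - ga[j]) / (ga[j + 1] - ga[j])
  ts <- pmin(pmax(ts, 0), 1); ta <- pmin(pmax(ta, 0), 1)
  z <- model$z
  z[cbind(i, j)] * (1 - ts) * (1 - ta) +
    z[cbind(i + 1L, j)] * ts * (1 - ta) +
    z[cbind(i, j + 1L)] * (1 - ts) * ta +
    z[cbind(i + 1L, j + 1L)] * ts * ta
}

#' Extract iso-resilience curves
#'
#' Contours of constant mean recovery time in the `(s, alpha)` plane — the
#' planner's indifference curves between connection quality and quantity.
#'
#' @param model a `surface_model`.
#' @param levels recovery-time level(s) to contour.
#' @return A list of polylines; each element is a `data.frame` with columns
#'   `level`, `s`, `alpha`. Empty list if no level intersects the surface.
#' @export
iso_contour <- function(model, levels) {
  cl <- grDevices::contourLines(x = model$s, y = model$alpha, z = model$z,
                                levels = levels)
  lapply(cl, function(p)
    data.frame(level = p$level, s = p$x, alpha = p$y))
}

#' Write iso-resilience curves to CSV
#'
#' @param contours result of [iso_contour].
#' @param path output path; columns `level,curve,point,s,alpha`.
#' @export
write_contours <- function(contours, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# iso-resilience contours: level,curve,point,s,alpha", con)
  writeLines("level,curve,point,s,alpha", con)
  for (ci in seq_along(contours)) {
    p <- contours[[ci]]
    writeLines(sprintf("%g,%d,%d,%.8g,%.8g", p$level, ci, seq_len(nrow(p)),
                       p$s, p$alpha), con)
  }
  invisible(path)
}

#' Linear conservation budget
#'
#' Affordability constraint `c_s * s + c_alpha * alpha <= budget`: a fixed
#' marginal cost for connection quality and for each connection. The axis
#' intercepts of the budget line are `budget / c_s` and `budget / c_alpha`.
#'
#' @param c_s cost per unit of connection quality (currency).
#' @param c_alpha cost per connection (currency).
#' @param budget total budget (currency); may be `NA` when only the cost
#'   structure is needed (e.g. [min_budget_for_target]).
#' @return An object of class `budget_model`.
#' @export
budget_model <- function(c_s, c_alpha, budget = NA_real_) {
  if (!is.finite(c_s) || c_s <= 0 || !is.finite(c_alpha) || c_alpha <= 0)
    stop("costs must be positive")
  structure(list(c_s = c_s, c_alpha = c_alpha, budget = budget),
            class = "budget_model")
}

#' @export
print.budget_model <- function(x, ...) {
  cat(sprintf("budget_model: cost = %g*s + %g*alpha%s\n", x$c_s, x$c_alpha,
              if (is.na(x$budget)) "" else sprintf(" <= %g", x$budget)))
  invisible(x)
}

offset_solution <- function(s, alpha, recovery_time, budget_required,
                            binding, offset = NA_real_) {
  structure(list(s = s, alpha = as.integer(round(alpha)),
                 alpha_exact = alpha, recovery_time = recovery_time,
                 budget_required = budget_required, binding = binding,
                 offset = offset),
            class = "offset_solution")
}

#' @export
print.offset_solution <- function(x, ...) {
  cat(sprintf("offset_solution: s = %.4f, alpha = %d -> recovery time %.3f\n",
              x$s, x$alpha, x$recovery_time))
  cat(sprintf("  budget required %.4g (binding: %s)%s\n", x$budget_required,
              paste(x$binding, collapse = ", "),
              if (is.na(x$offset)) "" else sprintf("; offset %.4g", x$offset)))
  invisible(x)
}

#' Best attainable resilience under a budget
#'
#' Minimizes interpolated mean recovery time over the affordable region
#' `c_s * s + c_alpha * alpha <= budget` intersected with box bounds —
#' the tangency point of the budget line with the outermost reachable
#' iso-resilience curve when the surface is strictly decreasing. Dense grid
#' search followed by one local refinement pass; ties broken toward lower
#' cost, then lower `s`. `alpha` is treated as continuous and rounded only
#' in the reported solution.
#'
#' @param model a `surface_model`.
#' @param budget a [budget_model] with a finite `budget`.
#' @param s_bounds,alpha_bounds box constraints (defaults: the grid domain).
#' @param n_grid search resolution per axis (default 401).
#' @return An `offset_solution`.
#' @export
optimize_under_budget <- function(model, budget, s_bounds = NULL,
                                  alpha_bounds = NULL, n_grid = 401L) {
  stopifnot(inherits(budget, "budget_model"), is.finite(budget$budget))
  if (is.null(s_bounds)) s_bounds <- range(model$s)
  if (is.null(alpha_bounds)) alpha_bounds <- range(model$alpha)
  s_bounds <- pmin(pmax(s_bounds, min(model$s)), max(model$s))
  alpha_bounds <- pmin(pmax(alpha_bounds, min(model$alpha)), max(model$alpha))
  search <- function(s_lo, s_hi, a_lo, a_hi) {
    sg <- seq(s_lo, s_hi, length.out = n_grid)
    ag <- seq(a_lo, a_hi, length.out = n_grid)
    g <- expand.grid(s = sg, alpha = ag)
    cost <- budget$c_s * g$s + budget$c_alpha * g$alpha
    feas <- cost <= budget$budget + 1e-9
    if (!any(feas)) return(NULL)
    g <- g[feas, ]; cost <- cost[feas]
    tt <- predict_surface(model, g$s, g$alpha)
    ord <- order(tt, cost, g$s)
    list(s = g$s[ord[1]], alpha = g$alpha[ord[1]], t = tt[ord[1]],
         cost = cost[ord[1]])
  }
  best <- search(s_bounds[1], s_bounds[2], alpha_bounds[1], alpha_bounds[2])
  if (is.null(best)) stop("empty feasible region: budget too small for bounds")
  ds <- diff(s_bounds) / (n_grid - 1); da <- diff(alpha_bounds) / (n_grid - 1)
  ref <- search(max(s_bounds[1], best$s - 2 * ds),
                min(s_bounds[2], best$s + 2 * ds),
                max(alpha_bounds[1], best$alpha - 2 * da),
                min(alpha_bounds[2], best$alpha + 2 * da))
  if (!is.null(ref) && ref$t <= best$t) best <- ref
  binding <- character(0)
  if (best$cost >= budget$budget - 1e-6 * max(1, budget$budget))
    binding <- c(binding, "budget")
  offset_solution(best$s, best$alpha, best$t, best$cost,
                  if (length(binding)) binding else "none")
}

#' Minimum budget to restore a target resilience under a connection cap
#'
#' The offset problem: after a permanent reduction caps the number of
#' connections at `alpha_cap`, find the cheapest `(s, alpha)` with
#' `alpha <= alpha_cap` whose mean recovery time does not exceed `target`.
#' For each candidate `alpha` the smallest feasible `s` is found by
#' bisection (recovery time is non-increasing in `s` on a smoothed surface);
#' the cost `c_s * s + c_alpha * alpha` is then minimized over the `alpha`
#' sweep. The returned `offset` is the extra budget relative to
#' `reference_budget` (e.g. the pre-disturbance budget), when given.
#'
#' @param model a `surface_model`.
#' @param target recovery-time level to restore.
#' @param alpha_cap maximum number of connections available.
#' @param budget a [budget_model] (its `budget` field is ignored; only the
#'   unit costs are used).
#' @param reference_budget optional baseline budget for the offset amount.
#' @param n_alpha resolution of the `alpha` sweep (default 401).
#' @return An `offset_solution`; errors if the target is unattainable even
#'   at `s = 1, alpha = alpha_cap`.
#' @export
min_budget_for_target <- function(model, target, alpha_cap, budget,
                                  reference_budget = NULL, n_alpha = 401L) {
  stopifnot(inherits(budget, "budget_model"))
  a_lo <- min(model$alpha)
  a_hi <- min(alpha_cap, max(model$alpha))
  if (a_hi < a_lo) stop("alpha_cap below the surface grid")
  s_lo <- min(model$s); s_hi <- max(model$s)
  if (predict_surface(model, s_hi, a_hi) > target + 1e-12)
    stop(sprintf("infeasible target %.4g: even s = %g, alpha = %g gives %.4g",
                 target, s_hi, a_hi,
                 predict_surface(model, s_hi, a_hi)))
  min_s_for <- function(a) {
    if (predict_surface(model, s_hi, a) > target + 1e-12) return(NA_real_)
    if (predict_surface(model, s_lo, a) <= target + 1e-12) return(s_lo)
    lo <- s_lo; hi <- s_hi
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (predict_surface(model, mid, a) <= target + 1e-12) hi <- mid
      else lo <- mid
    }
    hi
  }
  ag <- seq(a_lo, a_hi, length.out = n_alpha)
  sg <- vapply(ag, min_s_for, 1.0)
  feas <- !is.na(sg)
  costs <- budget$c_s * sg + budget$c_alpha * ag
  ord <- order(costs[feas], sg[feas])
  best_i <- which(feas)[ord[1]]
  s_star <- sg[best_i]; a_star <- ag[best_i]
  b_star <- costs[best_i]
  binding <- "target"
  if (abs(a_star - alpha_cap) < 1e-6 * max(1, alpha_cap))
    binding <- c(binding, "alpha_cap")
  offset <- if (is.null(reference_budget)) NA_real_ else b_star - reference_budget
  offset_solution(s_star, a_star, predict_surface(model, s_star, a_star),
                  b_star, binding, offset)
}
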