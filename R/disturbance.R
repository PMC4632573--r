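#' Construct a disturbance event
#'
#' A disturbance removes a fixed fraction of biomass from every
#' sub-population within a given radius of a centre point.
#'
#' @param centre_x,centre_y centre coordinates (model units).
#' @param radius disturbance radius in model units (default 0.4).
#' @param removal_fraction fraction of biomass removed from each affected
#'   sub-population, in `[0, 1]` (default 0.99).
#' @return An object of class `disturbance_event`.
#' @export
disturbance_event <- function(centre_x, centre_y, radius = 0.4,
                              removal_fraction = 0.99) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("removal_fraction must lie in [0, 1]")
  structure(list(centre = c(x = as.numeric(centre_x), y = as.numeric(centre_y)),
                 radius = radius, removal_fraction = removal_fraction),
            class = "disturbance_event")
}

#' @export
print.disturbance_event <- function(x, ...) {
  cat(sprintf("disturbance_event: centre (%.4g, %.4g), radius %g, removal %g%%\n",
              x$centre[1], x$centre[2], x$radius, 100 * x$removal_fraction))
  invisible(x)
}

#' Sample a spatially random disturbance event
#'
#' The centre is drawn uniformly on the axis-aligned bounding box of the node
#' coordinates. With `require_hit = TRUE` (the default) centres that disturb
#' no sub-population are redrawn, so every returned event removes biomass
#' somewhere; the number of draws used is attached as attribute `draws`.
#'
#' @param nodes a [reef_nodes] object.
#' @inheritParams disturbance_event
#' @param require_hit redraw until at least one node lies within the radius.
#' @param max_redraws safety cap on redraws (default 10000).
#' @return A [disturbance_event].
#' @export
sample_event <- function(nodes, radius = 0.4, removal_fraction = 0.99,
                         require_hit = TRUE, max_redraws = 10000L) {
  stopifnot(inherits(nodes, "reef_nodes"))
  bb <- c(min(nodes$x), max(nodes$x), min(nodes$y), max(nodes$y))
  draws <- 0L
  repeat {
    draws <- draws + 1L
    cx <- runif(1, bb[1], bb[2]); cy <- runif(1, bb[3], bb[4])
    ev <- disturbance_event(cx, cy, radius, removal_fraction)
    if (!require_hit || any(disturbed_set(ev, nodes))) break
    if (draws >= max_redraws)
      stop("no disturbance centre hit any node after ", max_redraws, " draws")
  }
  attr(ev, "draws") <- draws
  ev
}

#' Which sub-populations does an event disturb?
#'
#' @param event a [disturbance_event].
#' @param nodes a [reef_nodes] object.
#' @return Logical vector: `TRUE` where the node lies within the radius of
#'   the centre (boundary inclusive, `<= radius`).
#' @export
disturbed_set <- function(event, nodes) {
  stopifnot(inherits(event, "disturbance_event"), inherits(nodes, "reef_nodes"))
  d <- sqrt((nodes$x - event$centre[1])^2 + (nodes$y - event$centre[2])^2)
  d <= event$radius
}

#' Apply a disturbance to a biomass state
#'
#' @param state numeric biomass vector.
#' @param mask logical vector of disturbed nodes (see [disturbed_set]).
#' @param removal_fraction fraction removed from masked nodes.
#' @return The post-disturbance state: masked entries scaled by
#'   `1 - removal_fraction`, others bit-identical.
#' @export
apply_event <- function(state, mask, removal_fraction = 0.99) {
  if (length(mask) != length(state)) stop("mask length does not match state")
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("removal_fraction must lie in [0, 1]")
  state[mask] <- state[mask] * (1 - removal_fraction)
  state
}
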