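# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("divmap_input_error", "error", "condition")))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("divmap_fit_error", "error", "condition")))
}

#' Derive reproducible sub-stream seeds from one top-level seed
#'
#' All stochastic experiment drivers consume one top-level seed and derive
#' one independent sub-seed per repetition, so that repetitions are
#' reproducible individually and the whole experiment is reproducible as a
#' batch.
#'
#' @param seed integer top-level seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each a valid `set.seed()` argument.
#' @export
derive_seeds <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("seed must be a single finite number")
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Convex hull polygon (counter-clockwise, open ring) of a 2-column matrix.
convex_hull_polygon <- function(pts) {
  pts <- as.matrix(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

# Logical vector: which query points fall inside the convex hull of `sites`.
points_in_hull <- function(query, sites) {
  hull <- convex_hull_polygon(sites)
  if (nrow(hull) < 3L) stop_input("sites are collinear; convex hull is degenerate")
  ring <- rbind(hull, hull[1L, , drop = FALSE])
  mgcv::in.out(ring, as.matrix(query))
}

# Bilinear interpolation of V[ix, iy] sampled at (gx, gy), evaluated at
# (px, py). Points just outside the outermost nodes are extrapolated from
# the edge cell (callers enforce domain bounds).
bilinear_interp <- function(gx, gy, V, px, py) {
  ix <- findInterval(px, gx, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(gx) - 1L)
  iy <- findInterval(py, gy, rightmost.closed = TRUE)
  iy <- pmin(pmax(iy, 1L), length(gy) - 1L)
  wx <- (px - gx[ix]) / (gx[ix + 1L] - gx[ix])
  wy <- (py - gy[iy]) / (gy[iy + 1L] - gy[iy])
  V[cbind(ix, iy)] * (1 - wx) * (1 - wy) +
    V[cbind(ix + 1L, iy)] * wx * (1 - wy) +
    V[cbind(ix, iy + 1L)] * (1 - wx) * wy +
    V[cbind(ix + 1L, iy + 1L)] * wx * wy
}

# Rotation matrix for an angle in radians.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}
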