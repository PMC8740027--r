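# Augmented radial basis function interpolation of activation times with
# Duchon's cubic kernel R(r) = r^3 and a first-order polynomial tail
# P(x, y) = beta1 + beta2 x + beta3 y. The interpolant
#
#   f(X) = sum_i alpha_i ||X - X_i||^3 + beta1 + beta2 x + beta3 y
#
# is fitted by solving the symmetric (N+3) x (N+3) saddle-point system
# [K P; P' 0] [alpha; beta] = [t; 0], whose side constraints
# sum alpha_i = sum alpha_i x_i = sum alpha_i y_i = 0 make the kernel part
# orthogonal to affine fields and guarantee linear precision. First and
# second derivatives of f are available in closed form, which downstream
# modules use to compute velocity and divergence fields analytically.

#' Fit the cubic RBF interpolant to one beat of a recording
#'
#' Solves the saddle-point system for the Duchon cubic kernel with a linear
#' polynomial tail. Sites with a missing activation for the requested beat
#' are dropped from the fit (no imputation). For numerical conditioning the
#' coordinates are internally centered and scaled by the mean pairwise
#' distance before assembly; the returned weights are de-scaled back to mm
#' units, so `alpha` is in ms/mm^3 and `beta` in (ms, ms/mm, ms/mm).
#'
#' @param recording a [multisite_recording()].
#' @param beat beat (column) index to fit, default 1.
#' @return an `rbf_interpolant` with elements `centers` (N x 2 mm), `alpha`,
#'   `beta`, `beat_index`, `labels`.
#' @section Errors: fewer than 3 usable sites or collinear sites raise a
#'   `divmap_input_error`; a numerically singular system raises a
#'   `divmap_fit_error`.
#' @export
#' @examples
#' pos <- cbind(c(0, 10, 0, 10, 5), c(0, 0, 10, 10, 5))
#' rec <- multisite_recording(pos, 1 + 2 * pos[, 1] + 3 * pos[, 2])
#' m <- fit_interpolant(rec)
#' m$beta  # recovers (1, 2, 3): affine fields are reproduced exactly
fit_interpolant <- function(recording, beat = 1L) {
  stopifnot(inherits(recording, "multisite_recording"))
  if (beat < 1L || beat > ncol(recording$times))
    stop_input("beat index out of range")
  keep <- !is.na(recording$times[, beat])
  X <- recording$positions[keep, , drop = FALSE]
  t <- recording$times[keep, beat]
  n <- nrow(X)
  if (n < 3L) stop_input("fewer than 3 sites with a detected activation")
  sv <- svd(sweep(X, 2L, colMeans(X)))$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    stop_input("usable sites are collinear; interpolation is underdetermined")

  ctr <- colMeans(X)
  s <- mean(stats::dist(X))
  U <- sweep(X, 2L, ctr) / s

  D <- as.matrix(stats::dist(U))
  K <- D^3
  P <- cbind(1, U)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- c(t, 0, 0, 0)
  kap <- kappa(A, exact = FALSE)
  if (!is.finite(kap) || kap > 1e14)
    stop_fit("interpolation system is numerically singular (condition ~ ",
             format(kap, digits = 3), ")")
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop_fit("interpolation system could not be solved: ", conditionMessage(e)))

  alpha_s <- sol[seq_len(n)]
  beta_s <- sol[n + 1:3]
  # de-scale to mm units
  alpha <- unname(alpha_s / s^3)
  beta <- unname(c(beta_s[1L] - beta_s[2L] * ctr[1L] / s - beta_s[3L] * ctr[2L] / s,
                   beta_s[2L] / s, beta_s[3L] / s))
  structure(
    list(centers = X, alpha = alpha, beta = beta,
         beat_index = as.integer(beat),
         labels = recording$labels[keep]),
    class = "rbf_interpolant"
  )
}

#' @export
print.rbf_interpolant <- function(x, ...) {
  cat(sprintf("<rbf_interpolant> %d centers, beat %d\n",
              nrow(x$centers), x$beat_index))
  invisible(x)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_input("points must be an M x 2 matrix")
  points
}

# M x N matrices of differences and distances between evaluation points and
# centers; the shared kernel of all evaluators below.
model_geometry <- function(model, points) {
  cx <- model$centers[, 1L]; cy <- model$centers[, 2L]
  dx <- outer(points[, 1L], cx, `-`)
  dy <- outer(points[, 2L], cy, `-`)
  list(dx = dx, dy = dy, r = sqrt(dx * dx + dy * dy))
}

#' Evaluate the interpolated activation time
#'
#' @param model an `rbf_interpolant`.
#' @param points M x 2 matrix of evaluation positions (mm).
#' @return numeric vector of M activation times (ms).
#' @export
evaluate_time <- function(model, points) {
  stopifnot(inherits(model, "rbf_interpolant"))
  points <- as_points(points)
  g <- model_geometry(model, points)
  unname(drop((g$r^3) %*% model$alpha) +
           model$beta[1L] + model$beta[2L] * points[, 1L] +
           model$beta[3L] * points[, 2L])
}

#' Analytic gradient of the interpolated activation time
#'
#' Each kernel contributes `3 r d` to the gradient (`d` = point minus
#' center); at a center the contribution is the continuous limit `(0, 0)`.
#' The polynomial tail contributes `(beta2, beta3)`.
#'
#' @inheritParams evaluate_time
#' @return M x 2 matrix of gradients (ms/mm).
#' @export
evaluate_gradient <- function(model, points) {
  stopifnot(inherits(model, "rbf_interpolant"))
  points <- as_points(points)
  g <- model_geometry(model, points)
  gx <- drop((3 * g$r * g$dx) %*% model$alpha) + model$beta[2L]
  gy <- drop((3 * g$r * g$dy) %*% model$alpha) + model$beta[3L]
  cbind(x = gx, y = gy)
}

#' Analytic Hessian of the interpolated activation time
#'
#' Second derivatives of the cubic kernel are `3 r + 3 dx^2 / r`,
#' `3 r + 3 dy^2 / r` and `3 dx dy / r`, with limit 0 as `r -> 0`; the
#' polynomial tail contributes nothing.
#'
#' @inheritParams evaluate_time
#' @return M x 2 x 2 array of second derivatives (ms/mm^2).
#' @export
evaluate_hessian <- function(model, points) {
  stopifnot(inherits(model, "rbf_interpolant"))
  points <- as_points(points)
  g <- model_geometry(model, points)
  rinv <- ifelse(g$r > 0, 1 / g$r, 0)
  hxx <- drop((3 * g$r + 3 * g$dx^2 * rinv) %*% model$alpha)
  hyy <- drop((3 * g$r + 3 * g$dy^2 * rinv) %*% model$alpha)
  hxy <- drop((3 * g$dx * g$dy * rinv) %*% model$alpha)
  H <- array(0, dim = c(nrow(points), 2L, 2L))
  H[, 1L, 1L] <- hxx; H[, 2L, 2L] <- hyy
  H[, 1L, 2L] <- hxy; H[, 2L, 1L] <- hxy
  H
}

#' Serialize a fitted interpolant to JSON
#'
#' @param model an `rbf_interpolant`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @export
interpolant_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rbf_interpolant"))
  obj <- list(centers = unname(model$centers), alpha = unname(model$alpha),
              beta = unname(model$beta), beat_index = model$beat_index)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
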