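# Shared fixtures, built in code.

# random scattered recording with smooth (quadratic-ish) times
random_recording <- function(seed, n = 15L, extent = 24) {
  set.seed(seed)
  repeat {
    pos <- cbind(runif(n, -extent / 2, extent / 2),
                 runif(n, -extent / 2, extent / 2))
    if (min(dist(pos)) > 0.5) break
  }
  a <- rnorm(6, sd = c(10, 1, 1, 0.05, 0.05, 0.05))
  t <- a[1] + a[2] * pos[, 1] + a[3] * pos[, 2] +
    a[4] * pos[, 1]^2 + a[5] * pos[, 2]^2 + a[6] * pos[, 1] * pos[, 2]
  multisite_recording(pos, t)
}

# recording sampled from a radial (focal) time field t = ||x - s|| / c
radial_recording <- function(source = c(0, 0), speed_mm_ms = 0.546,
                             layout = pentaray_patch_layout()) {
  pos <- layout$points
  t <- sqrt((pos[, 1] - source[1])^2 + (pos[, 2] - source[2])^2) / speed_mm_ms
  multisite_recording(pos, t, labels = layout$labels)
}

# dense ring sampling of a radial field, for near-ideal reconstructions
dense_radial_recording <- function(source = c(0, 0), speed_mm_ms = 0.546,
                                   radii = seq(1, 12, by = 1),
                                   per_ring = 24L) {
  pts <- do.call(rbind, lapply(radii, function(r) {
    th <- seq(0, 2 * pi, length.out = per_ring + 1L)[-1L] + r
    cbind(source[1] + r * cos(th), source[2] + r * sin(th))
  }))
  t <- sqrt((pts[, 1] - source[1])^2 + (pts[, 2] - source[2])^2) / speed_mm_ms
  multisite_recording(pts, t)
}

# central finite-difference gradient of the interpolant (independent oracle)
fd_gradient <- function(model, points, h = 1e-4) {
  points <- matrix(points, ncol = 2)
  t(apply(points, 1, function(p) {
    c((evaluate_time(model, rbind(p + c(h, 0))) -
         evaluate_time(model, rbind(p - c(h, 0)))) / (2 * h),
      (evaluate_time(model, rbind(p + c(0, h))) -
         evaluate_time(model, rbind(p - c(0, h)))) / (2 * h))
  }))
}

# central finite differences of the analytic gradient (Hessian oracle)
fd_hessian <- function(model, points, h = 1e-4) {
  points <- matrix(points, ncol = 2)
  out <- array(0, dim = c(nrow(points), 2, 2))
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    gx <- (evaluate_gradient(model, rbind(p + c(h, 0))) -
             evaluate_gradient(model, rbind(p - c(h, 0)))) / (2 * h)
    gy <- (evaluate_gradient(model, rbind(p + c(0, h))) -
             evaluate_gradient(model, rbind(p - c(0, h)))) / (2 * h)
    out[k, , ] <- rbind(gx, gy)
  }
  out
}
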