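test_that("grids have uniform spacing and sensible masks", {
  lay <- pentaray_patch_layout()
  g <- make_grid(lay, resolution = 100)
  expect_s3_class(g, "eval_grid")
  expect_equal(diff(g$x), rep(g$h, 99), tolerance = 1e-12)
  expect_equal(diff(g$y), rep(g$h, 99), tolerance = 1e-12)
  # hull mask: nodes at the catheter center are in, corners are out
  i0 <- which.min(abs(g$x)); j0 <- which.min(abs(g$y))
  expect_true(g$mask[i0, j0])
  expect_false(g$mask[1, 1])
  expect_true(all(make_grid(lay, 50, mask_mode = "box")$mask))
  # cell-centered bounds mode: 200 nodes over a 40 mm patch = 0.2 mm cells
  gp <- make_grid(bounds = c(0, 40, 0, 40), resolution = 200,
                  mask_mode = "box")
  expect_equal(gp$h, 0.2)
  expect_equal(gp$x[1], 0.1)
  expect_error(make_grid(lay, resolution = 4), "at least 8")
})

test_that("velocity field recovers speed and direction of ideal patterns", {
  lay <- pentaray_patch_layout()
  # plane wave t = x / c
  c_mm <- 0.604  # mm/ms = 60.4 cm/s
  rec <- multisite_recording(lay$points, lay$points[, 1] / c_mm)
  vf <- velocity_field(fit_interpolant(rec), make_grid(lay, 60))
  expect_equal(median_speed(vf), 60.4, tolerance = 1e-9)
  expect_equal(max(abs(vf$unit_vy[vf$valid])), 0, tolerance = 1e-9)
  expect_true(all(vf$unit_vx[vf$valid] > 0.999999))
  # unit vectors have unit norm; speed * ||grad f|| is unit-consistent
  nrm <- sqrt(vf$unit_vx[vf$valid]^2 + vf$unit_vy[vf$valid]^2)
  expect_equal(nrm, rep(1, length(nrm)), tolerance = 1e-9)
  # radial field: unit vectors point away from the source
  src <- c(-2, 3)
  rec_r <- radial_recording(source = src)
  vf_r <- velocity_field(fit_interpolant(rec_r), make_grid(lay, 60))
  sel <- which(vf_r$valid, arr.ind = TRUE)
  keep <- sel[sqrt((vf_r$grid$x[sel[, 1]] - src[1])^2 +
                   (vf_r$grid$y[sel[, 2]] - src[2])^2) > 2, , drop = FALSE]
  dx <- vf_r$grid$x[keep[, 1]] - src[1]
  dy <- vf_r$grid$y[keep[, 2]] - src[2]
  dots <- (vf_r$unit_vx[keep] * dx + vf_r$unit_vy[keep] * dy) /
    sqrt(dx^2 + dy^2)
  expect_true(all(dots > 0.9))
})

test_that("speed, gradient norm and unit conversion are consistent", {
  rec <- random_recording(31)
  m <- fit_interpolant(rec)
  g <- make_grid(rec$positions, 40)
  vf <- velocity_field(m, g)
  nodes <- divmap:::grid_nodes(g)
  gn <- sqrt(rowSums(evaluate_gradient(m, nodes)^2))
  sel <- as.vector(vf$valid)
  expect_equal(vf$speed[vf$valid] * gn[sel], rep(100, sum(sel)),
               tolerance = 1e-9)
})

test_that("divergence estimators agree away from degenerate nodes", {
  rec <- random_recording(23)
  m <- fit_interpolant(rec)
  g <- make_grid(rec$positions, 80)
  d_an <- divergence_field(m, g, method = "analytic")
  d_gr <- divergence_field(m, g, method = "grid")
  vf <- velocity_field(m, g)
  both <- d_an$valid & d_gr$valid & vf$speed < 200 & abs(d_an$values) < 2
  expect_gt(sum(both, na.rm = TRUE), 100)
  expect_lt(max(abs(d_an$values[both] - d_gr$values[both])), 1e-2)
})

test_that("plane waves give near-zero divergence, sources positive, collisions negative", {
  lay <- pentaray_patch_layout()
  rec <- multisite_recording(lay$points, lay$points[, 1] / 0.604)
  g <- make_grid(lay, 60)
  for (mth in c("analytic", "grid")) {
    dv <- divergence_field(fit_interpolant(rec), g, method = mth)
    expect_lt(max(abs(dv$values[dv$valid])), 1e-9)
  }
  # focal recording: positive divergence at the source
  rec_f <- radial_recording()
  dv_f <- divergence_field(fit_interpolant(rec_f), g)
  i0 <- which.min(abs(g$x)); j0 <- which.min(abs(g$y))
  expect_gt(dv_f$values[i0, j0], 1)
  # two colliding plane waves: negative band along the equidistance line
  t_coll <- pmin(lay$points[, 1] + 15, 15 - lay$points[, 1]) / 0.604
  dv_c <- divergence_field(fit_interpolant(
    multisite_recording(lay$points, t_coll)), g)
  expect_lt(min(dv_c$values[dv_c$valid]), -1)
  mid <- dv_c$values[i0, ]
  expect_lt(median(mid, na.rm = TRUE), 0)
})

test_that("analytic divergence of a dense radial reconstruction approximates 1/r", {
  rec <- dense_radial_recording()
  m <- fit_interpolant(rec)
  g <- make_grid(rec$positions, 121)   # ~0.2 mm cells
  dv <- divergence_field(m, g, method = "analytic")
  sel <- which(dv$valid, arr.ind = TRUE)
  r <- sqrt(dv$grid$x[sel[, 1]]^2 + dv$grid$y[sel[, 2]]^2)
  keep <- r >= 2 * g$h & r <= 10
  expect_gt(sum(keep), 1000)
  rel <- abs(dv$values[sel[keep, , drop = FALSE]] - 1 / r[keep]) * r[keep]
  expect_lt(max(rel), 0.02)
})

test_that("divergence is rotation-equivariant and invariant to time rescaling", {
  rec <- random_recording(37)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g <- make_grid(rec$positions, 50, mask_mode = "box")
  m <- fit_interpolant(rec)
  dv <- divergence_field(m, g, method = "analytic")
  # rotate sites; evaluate on the rotated nodes
  rec_r <- multisite_recording(rec$positions %*% t(R), rec$times)
  m_r <- fit_interpolant(rec_r)
  nodes <- divmap:::grid_nodes(g)
  gr <- evaluate_gradient(m, nodes)
  gr_r <- evaluate_gradient(m_r, nodes %*% t(R))
  ang <- atan2(gr_r[, 2], gr_r[, 1]) - atan2(gr[, 2], gr[, 1])
  ang <- atan2(sin(ang), cos(ang))
  expect_equal(ang, rep(th, nrow(nodes)), tolerance = 1e-6)
  # uniform time rescaling leaves the unit-field divergence unchanged
  m_s <- fit_interpolant(multisite_recording(rec$positions, 3.7 * rec$times))
  dv_s <- divergence_field(m_s, g, method = "analytic")
  ok <- dv$valid & dv_s$valid & abs(dv$values) < 5
  expect_lt(max(abs(dv$values[ok] - dv_s$values[ok])), 1e-6)
})

test_that("median speed and vector-field averaging behave as expected", {
  # hand-built field with speeds 40/50/60 equally represented
  g <- make_grid(bounds = c(0, 3, 0, 3), resolution = 9, mask_mode = "box")
  blank <- matrix(NA_real_, 9, 9)
  vf <- structure(list(grid = g, vx = blank, vy = blank,
                       speed = matrix(rep(c(40, 50, 60), each = 27), 9, 9),
                       unit_vx = blank, unit_vy = blank,
                       valid = matrix(TRUE, 9, 9)), class = "vector_field")
  expect_equal(median_speed(vf), 50)
  # averaging a field with its negation yields zero vectors
  rec <- random_recording(41)
  m <- fit_interpolant(rec)
  gg <- make_grid(rec$positions, 30)
  f1 <- velocity_field(m, gg)
  f2 <- f1; f2$vx <- -f1$vx; f2$vy <- -f1$vy
  avg <- average_vector_fields(list(f1, f2))
  expect_lt(max(abs(avg$vx[avg$valid]), abs(avg$vy[avg$valid])), 1e-9)
  # majority validity rule
  f3 <- f1; f3$valid[] <- FALSE
  avg2 <- average_vector_fields(list(f1, f1, f3))
  expect_true(any(avg2$valid))
  avg3 <- average_vector_fields(list(f1, f3, f3))
  expect_false(any(avg3$valid))
})

test_that("field CSV export writes one row per masked node", {
  rec <- random_recording(43)
  g <- make_grid(rec$positions, 20)
  vf <- velocity_field(fit_interpolant(rec), g)
  path <- tempfile(fileext = ".csv")
  write_field_csv(vf, path)
  df <- read.csv(path)
  expect_equal(nrow(df), sum(g$mask))
  expect_true(all(c("x_mm", "y_mm", "speed_cm_s", "valid") %in% names(df)))
})
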