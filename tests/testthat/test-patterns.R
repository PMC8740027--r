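test_that("homogeneous patterns carry their exact configured median speed", {
  f <- simulate_activation_field(pattern_config("plane", time_quantum = 0))
  expect_equal(median(sqrt(f$vx^2 + f$vy^2)), 60.4, tolerance = 1e-12)
  f2 <- simulate_activation_field(pattern_config("focal_homogeneous",
                                                 time_quantum = 0))
  expect_equal(median(sqrt(f2$vx^2 + f2$vy^2), na.rm = TRUE), 54.6,
               tolerance = 1e-12)
  f3 <- simulate_activation_field(pattern_config("collision", time_quantum = 0))
  expect_equal(median(sqrt(f3$vx^2 + f3$vy^2)), 55.8, tolerance = 1e-12)
  # focal times are the radial travel time
  i <- 150; j <- 100
  r <- sqrt((f2$grid$x[i] - 20)^2 + (f2$grid$y[j] - 20)^2)
  expect_equal(f2$times[i, j], r / 0.546, tolerance = 1e-9)
})

test_that("collision times are continuous with a gradient break on the midline", {
  f <- simulate_activation_field(pattern_config("collision", time_quantum = 0))
  # continuity: finite differences along x bounded by h / c
  dx <- abs(diff(f$times[, 100]))
  expect_lt(max(dx), 1.01 * f$grid$h / 0.558)
  # direction flips across the midline
  expect_true(all(f$vx[f$grid$x < 19, ] > 0))
  expect_true(all(f$vx[f$grid$x > 21, ] < 0))
})

test_that("heterogeneous sector speeds emulate the intended dispersion", {
  st <- vapply(1:15, function(s) {
    f <- simulate_activation_field(
      pattern_config("focal_heterogeneous", grid_n = 80, seed = s))
    c(mean(f$speed_map), sd(f$speed_map))
  }, numeric(2))
  expect_equal(mean(st[1, ]), 59.9, tolerance = 1)   # cm/s
  expect_equal(mean(st[2, ]), 12.5, tolerance = 2)
  expect_true(all(st[1, ] > 20))
})

test_that("eikonal first-arrival matches the analytic radial field for uniform speed", {
  cfg <- pattern_config("focal_heterogeneous", grid_n = 150,
                        heterogeneity = list(cv_sd = 1e-9), time_quantum = 0,
                        seed = 3)
  f <- simulate_activation_field(cfg)
  r <- sqrt(outer((f$grid$x - 20)^2, (f$grid$y - 20)^2, `+`))
  exact <- r / (f$speed_map[1, 1] / 100)
  sel <- r >= 5 * f$grid$h
  expect_lt(max(abs(f$times[sel] - exact[sel]) / exact[sel]), 0.01)
})

test_that("simulation output is reproducible and quantized", {
  cfg <- pattern_config("focal_heterogeneous", grid_n = 60, seed = 8,
                        time_quantum = 1)
  f1 <- simulate_activation_field(cfg)
  f2 <- simulate_activation_field(cfg)
  expect_identical(f1$times, f2$times)
  expect_identical(f1$speed_map, f2$speed_map)
  expect_true(all(f1$times == round(f1$times)))  # 1 ms quantum
  # quantization moves any time by at most q/2
  cfg0 <- pattern_config("focal_homogeneous", time_quantum = 0)
  cfgq <- pattern_config("focal_homogeneous", time_quantum = 1)
  t0 <- simulate_activation_field(cfg0)$times
  tq <- simulate_activation_field(cfgq)$times
  expect_lte(max(abs(t0 - tq)), 0.5)
})

test_that("catheter sampling interpolates the field and replicates beats", {
  lay <- pentaray_patch_layout()
  f <- simulate_activation_field(pattern_config("plane"))
  rec <- sample_multisite(f, lay, n_beats = 2, cycle_length = 150)
  expect_equal(rec$times[, 2] - rec$times[, 1], rep(150, 15),
               ignore_attr = TRUE)
  # a site exactly on a grid node reports the grid value
  f0 <- simulate_activation_field(pattern_config("focal_homogeneous"))
  pts <- rbind(c(f0$grid$x[90], f0$grid$y[120]), c(10, 10), c(30, 30))
  lay3 <- divmap:::new_catheter_layout(sweep(pts, 2, c(20, 20)),
                                       c("a", "b", "c"), 20)
  rec3 <- sample_multisite(f0, lay3, center = c(20, 20))
  expect_equal(unname(rec3$times[1, 1]), f0$times[90, 120], tolerance = 1e-12)
  # focal pattern activates inner bipoles before outer ones
  recf <- sample_multisite(f0, lay, center = f0$source)
  t34 <- recf$times[grepl("_34$", recf$labels), 1]
  t12 <- recf$times[grepl("_12$", recf$labels), 1]
  expect_true(all(t34 < t12))
  # placements outside the patch are rejected
  expect_error(sample_multisite(f0, lay, center = c(2, 2)), "outside")
})

test_that("jitter respects amplitude conventions and reproducibility", {
  lay <- pentaray_patch_layout()
  f <- simulate_activation_field(pattern_config("plane"))
  rec <- sample_multisite(f, lay, n_beats = 50)
  expect_identical(add_jitter(rec, 0), rec)
  j1 <- add_jitter(rec, 0.10, seed = 7)
  j2 <- add_jitter(rec, 0.10, seed = 7)
  expect_identical(j1$times, j2$times)
  # full-width: |jitter| <= eps/2 = 7.5 ms, SD = 7.5/sqrt(3)
  d_full <- (j1$times - rec$times)
  expect_lte(max(abs(d_full)), 7.5)
  # half-width: |jitter| <= 15 ms, SD = 15/sqrt(3) (uniform moments)
  jh <- add_jitter(rec, 0.10, seed = 7, convention = "half_width")
  d_half <- jh$times - rec$times
  expect_lte(max(abs(d_half)), 15)
  expect_gt(max(abs(d_half)), 7.5)
  expect_equal(sd(d_half), 15 / sqrt(3), tolerance = 0.05)
  expect_error(add_jitter(rec, 0.7), "eps_fraction")
})

test_that("site removal keeps all beats aligned and enforces the minimum", {
  lay <- pentaray_patch_layout()
  f <- simulate_activation_field(pattern_config("focal_homogeneous"))
  rec <- sample_multisite(f, lay, center = f$source, n_beats = 3)
  expect_identical(remove_sites(rec, 0), rec)
  r6 <- remove_sites(rec, 6, seed = 2)
  expect_equal(nrow(r6$positions), 9L)
  expect_true(all(r6$labels %in% rec$labels))
  kept <- match(r6$labels, rec$labels)
  expect_equal(r6$times, rec$times[kept, ], tolerance = 1e-12)
  expect_error(remove_sites(rec, 13), "at least 3")
})
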