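test_that("affine activation fields are reproduced exactly (linear precision)", {
  set.seed(42)
  pos <- cbind(runif(15, -12, 12), runif(15, -12, 12))
  rec <- multisite_recording(pos, 1 + 2 * pos[, 1] + 3 * pos[, 2])
  m <- fit_interpolant(rec)
  expect_lt(max(abs(m$alpha)), 1e-9)
  expect_equal(unname(m$beta), c(1, 2, 3), tolerance = 1e-9)
  # closed-form evaluation away from the sites
  expect_equal(evaluate_time(m, c(10, -5)), 1 + 20 - 15, tolerance = 1e-9)
  # gradient constant, Hessian zero
  g <- evaluate_gradient(m, rbind(c(3, 3), c(-7, 2)))
  expect_equal(unname(g), rbind(c(2, 3), c(2, 3)), tolerance = 1e-9)
  H <- evaluate_hessian(m, rbind(c(3, 3)))
  expect_lt(max(abs(H)), 1e-9)
})

test_that("interpolation and orthogonality constraints hold on random recordings", {
  for (seed in 1:25) {
    rec <- random_recording(seed)
    m <- fit_interpolant(rec)
    resid <- evaluate_time(m, rec$positions) - rec$times[, 1]
    scale <- max(1, max(abs(rec$times)))
    expect_lt(max(abs(resid)), 1e-8 * scale)
    expect_lt(abs(sum(m$alpha)), 1e-8)
    expect_lt(abs(sum(m$alpha * m$centers[, 1])), 1e-8)
    expect_lt(abs(sum(m$alpha * m$centers[, 2])), 1e-8)
  }
})

test_that("evaluation agrees with a term-by-term brute-force sum", {
  rec <- random_recording(7)
  m <- fit_interpolant(rec)
  set.seed(99)
  pts <- cbind(runif(20, -15, 15), runif(20, -15, 15))
  brute <- sapply(seq_len(nrow(pts)), function(k) {
    s <- m$beta[1] + m$beta[2] * pts[k, 1] + m$beta[3] * pts[k, 2]
    for (i in seq_len(nrow(m$centers)))
      s <- s + m$alpha[i] * sqrt(sum((pts[k, ] - m$centers[i, ])^2))^3
    s
  })
  expect_equal(evaluate_time(m, pts), brute, tolerance = 1e-10)
})

test_that("analytic derivatives match finite-difference oracles", {
  for (seed in c(3, 11, 21)) {
    rec <- random_recording(seed)
    m <- fit_interpolant(rec)
    set.seed(seed + 100)
    pts <- cbind(runif(12, -10, 10), runif(12, -10, 10))
    g <- evaluate_gradient(m, pts)
    g_fd <- fd_gradient(m, pts)
    expect_equal(unname(g), unname(g_fd),
                 tolerance = 1e-5 * max(1, max(abs(g))))
    H <- evaluate_hessian(m, pts)
    H_fd <- fd_hessian(m, pts)
    expect_equal(H, H_fd, tolerance = 1e-4 * max(1, max(abs(H))))
    expect_equal(H[, 1, 2], H[, 2, 1])  # symmetric exactly
  }
})

test_that("gradient is continuous at a center", {
  rec <- radial_recording()
  m <- fit_interpolant(rec)
  ctr <- m$centers[4, ]
  g0 <- evaluate_gradient(m, rbind(ctr))
  expect_true(all(is.finite(g0)))
  near <- evaluate_gradient(m, rbind(ctr + 1e-6, ctr - 1e-6))
  expect_equal(unname(g0[rep(1, 2), ]), unname(near), tolerance = 1e-4)
})

test_that("fit is invariant to site order and equivariant under rigid motion", {
  rec <- random_recording(5)
  perm <- sample(nrow(rec$positions))
  rec_p <- multisite_recording(rec$positions[perm, ], rec$times[perm, ],
                               rec$cycle_length)
  pts <- cbind(c(1, -4, 7), c(2, 5, -3))
  expect_equal(evaluate_time(fit_interpolant(rec), pts),
               evaluate_time(fit_interpolant(rec_p), pts), tolerance = 1e-9)
  # rigid motion of sites and evaluation points leaves times unchanged
  th <- 0.7; shift <- c(30, -12)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rec_r <- multisite_recording(sweep(rec$positions %*% t(R), 2, shift, `+`),
                               rec$times, rec$cycle_length)
  expect_equal(evaluate_time(fit_interpolant(rec), pts),
               evaluate_time(fit_interpolant(rec_r),
                             sweep(pts %*% t(R), 2, shift, `+`)),
               tolerance = 1e-9)
})

test_that("degenerate inputs raise typed errors", {
  pos <- cbind(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_error(multisite_recording(pos[1:2, ], 1:2), "3 sites")
  expect_error(fit_interpolant(multisite_recording(pos, c(1, 2, 3, 4))),
               class = "divmap_input_error")
  # duplicate positions are rejected, not averaged
  expect_error(multisite_recording(rbind(c(0, 0), c(0, 0), c(1, 1)), 1:3),
               "duplicate")
})

test_that("missing activations drop sites from that beat's fit only", {
  rec <- random_recording(9)
  times <- cbind(rec$times[, 1], rec$times[, 1] + 150)
  times[4, 2] <- NA
  rec2 <- multisite_recording(rec$positions, times)
  m2 <- fit_interpolant(rec2, beat = 2)
  expect_equal(nrow(m2$centers), 14L)
  expect_false("S4" %in% m2$labels)
  m1 <- fit_interpolant(rec2, beat = 1)
  expect_equal(nrow(m1$centers), 15L)
  # fewer than 3 usable sites is an input error
  times[, 2] <- NA
  times[1:2, 2] <- 0
  expect_error(fit_interpolant(multisite_recording(rec$positions, times), 2),
               class = "divmap_input_error")
})

test_that("model JSON export restores an equivalent interpolant", {
  rec <- random_recording(13)
  m <- fit_interpolant(rec)
  path <- tempfile(fileext = ".json")
  interpolant_to_json(m, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$alpha, unname(m$alpha), tolerance = 1e-12)
  expect_equal(obj$beta, unname(m$beta), tolerance = 1e-12)
  expect_equal(obj$beat_index, 1L)
})

test_that("recording CSV round-trips including missing cells", {
  rec <- random_recording(17)
  times <- cbind(rec$times[, 1], rec$times[, 1] + 150)
  times[2, 2] <- NA
  rec2 <- multisite_recording(rec$positions, times, cycle_length = 150)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec2, path)
  back <- read_recording_csv(path, cycle_length = 150)
  expect_equal(back$positions, rec2$positions, tolerance = 1e-12)
  expect_equal(back$times, rec2$times, tolerance = 1e-12)
  expect_true(is.na(back$times[2, 2]))
})
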