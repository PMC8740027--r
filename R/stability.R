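# Monte-Carlo stability experiments: reconstruct each simulated pattern
# through the catheter under progressive corruption (site removal or
# activation-time jitter), compare the estimated conduction-velocity field
# with the dense ground truth node by node inside the convex hull of the
# available sites, and aggregate median (IQR) metrics over repetitions.
# Focal-source localization robustness is assessed the same way with a
# randomly placed catheter.

#' Median pointwise conduction-speed error
#'
#' Median over valid overlapping nodes of
#' `100 * | ||v_est|| - ||v_true|| | / ||v_true||`, with the estimated field
#' evaluated on the truth grid (see [field_grid()]).
#'
#' @param est a `vector_field` on the truth grid.
#' @param truth the `activation_field` ground truth.
#' @return median absolute speed error (percent).
#' @export
pointwise_speed_error <- function(est, truth) {
  stopifnot(inherits(est, "vector_field"), inherits(truth, "activation_field"))
  check_truth_alignment(est, truth)
  sp_true <- sqrt(truth$vx^2 + truth$vy^2)
  ok <- est$valid & is.finite(sp_true)
  if (!any(ok)) stop_input("no overlapping valid nodes")
  median(100 * abs(est$speed[ok] - sp_true[ok]) / sp_true[ok])
}

#' Median pointwise conduction-direction error
#'
#' Median over valid overlapping nodes of the absolute angle (radians, in
#' `[0, pi]`) between estimated and true unit velocity vectors.
#'
#' @inheritParams pointwise_speed_error
#' @return median absolute angle error (rad).
#' @export
pointwise_angle_error <- function(est, truth) {
  stopifnot(inherits(est, "vector_field"), inherits(truth, "activation_field"))
  check_truth_alignment(est, truth)
  sp_true <- sqrt(truth$vx^2 + truth$vy^2)
  ok <- est$valid & is.finite(sp_true) & sp_true > 0
  if (!any(ok)) stop_input("no overlapping valid nodes")
  dotp <- (est$unit_vx[ok] * truth$vx[ok] + est$unit_vy[ok] * truth$vy[ok]) /
    sp_true[ok]
  median(acos(pmin(1, pmax(-1, dotp))))
}

check_truth_alignment <- function(est, truth) {
  if (!isTRUE(all.equal(est$grid$x, truth$grid$x)) ||
      !isTRUE(all.equal(est$grid$y, truth$grid$y)))
    stop_input("estimated field is not on the truth grid; use field_grid()")
}

iqr_fmt <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  c(median = q[1L], q25 = q[2L], q75 = q[3L])
}

experiment_row <- function(pattern, perturbation, level, n_beats, exact,
                           speeds, serrs, aerrs, n_reps, n_fail) {
  data.frame(
    pattern = pattern, perturbation = perturbation, level = level,
    n_beats = n_beats, exact_median_speed = exact,
    est_median_speed = iqr_fmt(speeds)[1L],
    est_median_speed_q25 = iqr_fmt(speeds)[2L],
    est_median_speed_q75 = iqr_fmt(speeds)[3L],
    speed_error_pct = iqr_fmt(serrs)[1L],
    speed_error_q25 = iqr_fmt(serrs)[2L],
    speed_error_q75 = iqr_fmt(serrs)[3L],
    angle_error_rad = iqr_fmt(aerrs)[1L],
    angle_error_q25 = iqr_fmt(aerrs)[2L],
    angle_error_q75 = iqr_fmt(aerrs)[3L],
    n_repetitions = n_reps, n_fit_failures = n_fail,
    row.names = NULL)
}

# Shared setup: simulate the pattern and sample the patch-centered catheter
# (for focal patterns the source coincides with the catheter center, the
# fixed placement used for the error-metric experiments).
stability_setup <- function(pattern, layout, n_beats = 1L, config = NULL,
                            seed = 1L) {
  config <- config %||% pattern_config(pattern, seed = seed)
  field <- simulate_activation_field(config)
  center <- if (!is.null(field$source)) field$source else
    rep(config$patch_size / 2, 2L)
  rec <- sample_multisite(field, layout, center = center, n_beats = n_beats)
  list(config = config, field = field, rec = rec, center = center)
}

#' Site-removal stability experiment
#'
#' For each removal level, repeats: remove that many randomly chosen sites,
#' fit the interpolant, evaluate the velocity field on the truth-grid nodes
#' inside the convex hull of the remaining sites, and compute median
#' pointwise speed/angle errors and the estimated median speed. The
#' catheter is patch-centered (source-centered for focal patterns); zero
#' removal is deterministic and evaluated once.
#'
#' @param pattern pattern name, see [pattern_config()].
#' @param n_removed vector of removal counts.
#' @param n_reps stochastic repetitions per level (default 100).
#' @param seed top-level seed.
#' @param layout catheter layout (default [pentaray_patch_layout()]).
#' @param config optional [pattern_config()] override.
#' @return data frame of one row per level with median (q25, q75) metrics.
#' @export
run_removal_experiment <- function(pattern, n_removed = c(0L, 2L, 4L, 6L, 8L, 10L),
                                   n_reps = 100L, seed = 1L,
                                   layout = pentaray_patch_layout(),
                                   config = NULL) {
  st <- stability_setup(pattern, layout, n_beats = 1L, config = config,
                        seed = seed)
  rows <- lapply(n_removed, function(k) {
    reps <- if (k == 0L) 1L else n_reps
    seeds <- derive_seeds(seed + 1000L * k, reps)
    speeds <- serrs <- aerrs <- rep(NA_real_, reps)
    fail <- 0L
    for (i in seq_len(reps)) {
      rec_i <- remove_sites(st$rec, k, seed = seeds[i])
      res <- tryCatch({
        model <- fit_interpolant(rec_i, 1L)
        grid <- field_grid(st$field, hull_of = rec_i$positions)
        est <- velocity_field(model, grid)
        c(median_speed(est), pointwise_speed_error(est, st$field),
          pointwise_angle_error(est, st$field))
      }, divmap_fit_error = function(e) NULL)
      if (is.null(res)) { fail <- fail + 1L; next }
      speeds[i] <- res[1L]; serrs[i] <- res[2L]; aerrs[i] <- res[3L]
    }
    ok <- !is.na(speeds)
    experiment_row(pattern, "removal", k, 1L, exact_speed(st$field),
                   speeds[ok], serrs[ok], aerrs[ok], reps, fail)
  })
  do.call(rbind, rows)
}

exact_speed <- function(field) {
  median(sqrt(field$vx^2 + field$vy^2), na.rm = TRUE)
}

# node-wise scalar mean of per-beat speed maps (majority validity rule)
average_speed_matrix <- function(fields) {
  nvalid <- Reduce(`+`, lapply(fields, function(f) f$valid * 1))
  ssum <- Reduce(`+`, lapply(fields, function(f) ifelse(f$valid, f$speed, 0)))
  ifelse(nvalid > length(fields) / 2, ssum / nvalid, NA_real_)
}

speed_error_from_matrix <- function(spm, truth) {
  sp_true <- sqrt(truth$vx^2 + truth$vy^2)
  ok <- is.finite(spm) & is.finite(sp_true)
  if (!any(ok)) stop_input("no overlapping valid nodes")
  median(100 * abs(spm[ok] - sp_true[ok]) / sp_true[ok])
}

#' Activation-time jitter stability experiment
#'
#' For each noise level, repeats: jitter every beat's activation times
#' independently, fit per beat and evaluate on the truth grid inside the
#' catheter hull. With `n_beats > 1` the per-beat estimates are averaged
#' node-wise before computing errors: conduction speeds as the scalar mean
#' of the per-beat speed maps (magnitude metrics and the estimated median
#' speed), directions as the node-wise vector mean (angle metric).
#' Averaging magnitudes rather than full vectors matters: with noisy
#' directions a vector mean systematically shrinks, biasing speeds low.
#' Zero noise is deterministic and evaluated once.
#'
#' @param eps vector of noise amplitudes as fractions of the cycle length.
#' @param n_beats beats to average over, e.g. `c(1, 10)`; one output row
#'   per (eps, n_beats) pair, sharing the per-repetition jitter draws so
#'   columns are paired.
#' @param jitter_convention passed to [add_jitter()].
#' @inheritParams run_removal_experiment
#' @return data frame of one row per (eps, n_beats) combination.
#' @export
run_noise_experiment <- function(pattern,
                                 eps = c(0, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20),
                                 n_beats = c(1L, 10L), n_reps = 100L,
                                 seed = 1L, layout = pentaray_patch_layout(),
                                 config = NULL,
                                 jitter_convention = "full_width") {
  nb_max <- max(n_beats)
  st <- stability_setup(pattern, layout, n_beats = nb_max, config = config,
                        seed = seed)
  grid <- field_grid(st$field, hull_of = st$rec$positions)
  rows <- list()
  for (e in eps) {
    reps <- if (e == 0) 1L else n_reps
    seeds <- derive_seeds(seed + round(1e6 * e), reps)
    acc <- lapply(n_beats, function(nb)
      list(speeds = rep(NA_real_, reps), serrs = rep(NA_real_, reps),
           aerrs = rep(NA_real_, reps), fail = 0L))
    names(acc) <- as.character(n_beats)
    for (i in seq_len(reps)) {
      rec_i <- add_jitter(st$rec, e, seed = seeds[i],
                          convention = jitter_convention)
      beat_fields <- vector("list", nb_max)
      for (b in seq_len(nb_max)) {
        beat_fields[[b]] <- tryCatch(
          velocity_field(fit_interpolant(rec_i, b), grid),
          divmap_fit_error = function(e2) NULL)
      }
      for (nb in n_beats) {
        key <- as.character(nb)
        fs <- beat_fields[seq_len(nb)]
        if (any(vapply(fs, is.null, TRUE))) {
          acc[[key]]$fail <- acc[[key]]$fail + 1L
          next
        }
        if (nb == 1L) {
          est <- fs[[1L]]
          acc[[key]]$speeds[i] <- median_speed(est)
          acc[[key]]$serrs[i] <- pointwise_speed_error(est, st$field)
          acc[[key]]$aerrs[i] <- pointwise_angle_error(est, st$field)
        } else {
          spm <- average_speed_matrix(fs)
          acc[[key]]$speeds[i] <- median(spm, na.rm = TRUE)
          acc[[key]]$serrs[i] <- speed_error_from_matrix(spm, st$field)
          acc[[key]]$aerrs[i] <-
            pointwise_angle_error(average_vector_fields(fs), st$field)
        }
      }
    }
    for (nb in n_beats) {
      a <- acc[[as.character(nb)]]
      ok <- !is.na(a$speeds)
      rows[[length(rows) + 1L]] <-
        experiment_row(pattern, "noise", e, nb, exact_speed(st$field),
                       a$speeds[ok], a$serrs[ok], a$aerrs[ok], reps, a$fail)
    }
  }
  do.call(rbind, rows)
}

#' Focal-source localization robustness sweep
#'
#' Repeats, per corruption level: place the catheter at a random center
#' (uniform over positions keeping the whole layout inside the patch and
#' the source inside the swept area) with a random rotation, corrupt the
#' recording (site removal or per-beat jitter), fit per beat, compute
#' divergence maps on the truth-grid nodes inside the catheter hull,
#' average maps when `n_beats > 1`, locate the source at the map maximum
#' and record its distance to the true source. Reports the median distance
#' per level and whether it beats the chance-level threshold.
#'
#' @param tissue `"homogeneous"` or `"heterogeneous"` conduction; the
#'   heterogeneous speed map is redrawn per repetition.
#' @param axis `"removal"` (levels = number of sites removed) or `"noise"`
#'   (levels = jitter fraction of cycle length).
#' @param levels corruption levels; defaults `0:7` sites or
#'   `c(0, .02, .05, .10, .15, .20)`.
#' @param n_beats beats per repetition (divergence maps averaged).
#' @inheritParams run_noise_experiment
#' @return data frame per level: `median_distance_mm` (q25, q75),
#'   `accurate` (median < threshold), `threshold_mm`, failure count.
#' @export
run_localization_sweep <- function(tissue = c("homogeneous", "heterogeneous"),
                                   axis = c("removal", "noise"),
                                   levels = NULL, n_beats = 1L,
                                   n_reps = 100L, seed = 1L,
                                   layout = pentaray_patch_layout(),
                                   jitter_convention = "full_width") {
  tissue <- match.arg(tissue)
  axis <- match.arg(axis)
  levels <- levels %||%
    if (axis == "removal") 0:7 else c(0, 0.02, 0.05, 0.10, 0.15, 0.20)
  pattern <- paste0("focal_", tissue)
  thr <- localization_threshold(layout$swept_radius)
  base_cfg <- pattern_config(pattern, seed = seed)
  src <- base_cfg$source_position
  R <- layout$swept_radius
  ps <- base_cfg$patch_size
  margin <- R + 1e-9

  hom_field <- if (tissue == "homogeneous")
    simulate_activation_field(base_cfg) else NULL

  rows <- lapply(seq_along(levels), function(li) {
    lev <- levels[li]
    seeds <- derive_seeds(seed + 7919L * li, n_reps)
    dists <- rep(NA_real_, n_reps)
    fail <- 0L
    for (i in seq_len(n_reps)) {
      set.seed(seeds[i])
      field <- if (tissue == "heterogeneous")
        simulate_activation_field(
          pattern_config(pattern, seed = seeds[i])) else hom_field
      # random center: source within swept area, layout inside patch
      repeat {
        u <- runif(2, -R, R)
        ctr <- src + u
        if (sum(u^2) <= R^2 && all(ctr >= margin) && all(ctr <= ps - margin))
          break
      }
      rot <- runif(1, 0, 2 * pi)
      res <- tryCatch({
        rec <- sample_multisite(field, layout, center = ctr, rotation = rot,
                                n_beats = n_beats)
        rec <- if (axis == "removal")
          remove_sites(rec, lev, seed = seeds[i]) else
          add_jitter(rec, lev, seed = seeds[i],
                     convention = jitter_convention)
        grid <- field_grid(field, hull_of = rec$positions)
        maps <- lapply(seq_len(n_beats), function(b)
          divergence_field(fit_interpolant(rec, b), grid))
        map <- if (n_beats == 1L) maps[[1L]] else average_divergence_maps(maps)
        loc <- locate_focal_source(map)
        assess_localization(loc, field$source, thr)$distance
      }, divmap_fit_error = function(e) NULL)
      if (is.null(res)) fail <- fail + 1L else dists[i] <- res
    }
    ok <- !is.na(dists)
    q <- iqr_fmt(dists[ok])
    data.frame(tissue = tissue, axis = axis, level = lev, n_beats = n_beats,
               median_distance_mm = q[1L], distance_q25 = q[2L],
               distance_q75 = q[3L], accurate = q[1L] < thr,
               threshold_mm = thr, n_repetitions = n_reps,
               n_fit_failures = fail, row.names = NULL)
  })
  do.call(rbind, rows)
}
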