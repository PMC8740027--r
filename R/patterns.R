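# Tissue-patch activation-pattern simulator. Generates dense ground-truth
# first-activation-time fields for four canonical patterns (plane wave,
# focal source in homogeneous and in heterogeneous tissue, wavefront
# collision) on a cell-centered square grid, together with the exact
# conduction-velocity vectors; samples them through a placed catheter over
# multiple beats; and applies the corruption models used in the stability
# experiments (uniform activation-time jitter, random site removal).
#
# Homogeneous patterns are written in closed form; the heterogeneous focal
# pattern solves the eikonal equation by fast marching over a speed map of
# angular sectors around the source. Activation times are quantized to a
# configurable time quantum (default 0.1 ms, the substrate-model temporal
# resolution; 1 ms emulates 1 kHz annotation).

#' Configuration of a simulated activation pattern
#'
#' @param pattern one of `"plane"`, `"focal_homogeneous"`,
#'   `"focal_heterogeneous"`, `"collision"`.
#' @param patch_size patch side (mm), default 40.
#' @param grid_n nodes per side of the down-sampled output grid (>= 50),
#'   default 200 (0.2 mm cells on the default patch).
#' @param speed conduction speed (cm/s). Defaults: plane 60.4, homogeneous
#'   focal 54.6, collision 55.8; for the heterogeneous focal pattern this is
#'   the sector-mean (default 60, see `heterogeneity`).
#' @param heterogeneity list for the heterogeneous pattern: `n_regions`
#'   angular sectors around the source (8), per-sector speeds drawn from
#'   Normal(`cv_mean` = 60, `cv_sd` = 13) cm/s truncated below at
#'   `cv_floor` = 20 cm/s. With 8 sectors the expected realized field is
#'   about 60 +/- 12.5 cm/s (the sample SD of 8 normal draws).
#' @param source_position focal source (mm), default patch center.
#' @param wave_direction unit direction of the plane wave (and of the first
#'   colliding wave; the second travels opposite), default `c(1, 0)`.
#' @param cycle_length activation cycle length (ms), default 150.
#' @param time_quantum activation-time quantum (ms), default 0.1 -- the
#'   temporal resolution of the excitable-substrate models this generator
#'   emulates; set 1 to emulate 1 kHz annotation quantization, 0 for ideal
#'   continuous-time fields.
#' @param seed RNG seed for the heterogeneous speed draw.
#' @return a `pattern_config`.
#' @export
pattern_config <- function(pattern = c("plane", "focal_homogeneous",
                                       "focal_heterogeneous", "collision"),
                           patch_size = 40, grid_n = 200L, speed = NULL,
                           heterogeneity = list(), source_position = NULL,
                           wave_direction = c(1, 0), cycle_length = 150,
                           time_quantum = 0.1, seed = 1L) {
  pattern <- match.arg(pattern)
  if (grid_n < 50L) stop_input("grid_n must be at least 50")
  if (patch_size <= 0) stop_input("patch_size must be positive")
  speed <- speed %||% switch(pattern,
    plane = 60.4, focal_homogeneous = 54.6,
    focal_heterogeneous = 60, collision = 55.8)
  if (speed <= 0) stop_input("speed must be positive")
  het <- utils::modifyList(
    list(n_regions = 8L, cv_mean = 60, cv_sd = 13, cv_floor = 20),
    heterogeneity)
  src <- source_position %||% rep(patch_size / 2, 2L)
  if (pattern %in% c("focal_homogeneous", "focal_heterogeneous") &&
      (any(src <= 0) || any(src >= patch_size)))
    stop_input("source must lie inside the patch")
  wd <- as.numeric(wave_direction)
  wd <- wd / sqrt(sum(wd^2))
  structure(
    list(pattern = pattern, patch_size = patch_size, grid_n = as.integer(grid_n),
         speed = speed, heterogeneity = het, source_position = as.numeric(src),
         wave_direction = wd, cycle_length = cycle_length,
         time_quantum = time_quantum, seed = as.integer(seed)),
    class = "pattern_config"
  )
}

cm_s_to_mm_ms <- function(v) v / 100

#' Simulate a ground-truth activation field
#'
#' Produces first-activation times and exact conduction-velocity vectors on
#' the cell-centered `grid_n` x `grid_n` grid. Closed forms are used for
#' the homogeneous patterns (plane: `t = d.x/c`; focal: `t = ||x - s||/c`;
#' collision: pointwise minimum of two opposing plane waves); the
#' heterogeneous focal pattern is solved by second-order fast marching over
#' the sector speed map, with its true velocity taken from the (central
#' finite difference) gradient of the unquantized arrival times. Times are
#' quantized to `time_quantum` afterwards; the stored true vectors are
#' unaffected by quantization.
#'
#' @param config a [pattern_config()].
#' @return an `activation_field`: `grid` (cell-centered `x`, `y`, spacing
#'   `h`), `times` (ms, matrix `[i, j]` = node `(x[i], y[j])`), `vx`, `vy`
#'   (true CV, cm/s), `speed_map` (cm/s; heterogeneous pattern only),
#'   `source` (mm or `NULL`), `config`.
#' @export
simulate_activation_field <- function(config) {
  stopifnot(inherits(config, "pattern_config"))
  n <- config$grid_n
  h <- config$patch_size / n
  gx <- (seq_len(n) - 0.5) * h
  gy <- gx
  X <- matrix(rep(gx, times = n), n, n)
  Y <- matrix(rep(gy, each = n), n, n)
  c_mm <- cm_s_to_mm_ms(config$speed)
  src <- NULL
  speed_map <- NULL

  if (config$pattern == "plane") {
    d <- config$wave_direction
    proj <- d[1L] * X + d[2L] * Y
    times <- (proj - min(proj)) / c_mm
    vx <- matrix(config$speed * d[1L], n, n)
    vy <- matrix(config$speed * d[2L], n, n)
  } else if (config$pattern == "focal_homogeneous") {
    src <- config$source_position
    dx <- X - src[1L]; dy <- Y - src[2L]
    r <- sqrt(dx^2 + dy^2)
    times <- r / c_mm
    vx <- config$speed * ifelse(r > 0, dx / r, NA_real_)
    vy <- config$speed * ifelse(r > 0, dy / r, NA_real_)
  } else if (config$pattern == "collision") {
    d <- config$wave_direction
    proj <- d[1L] * X + d[2L] * Y
    t1 <- (proj - min(proj)) / c_mm          # wave along +d
    t2 <- (max(proj) - proj) / c_mm          # opposing wave
    times <- pmin(t1, t2)
    first <- t1 <= t2                        # tie: first wave
    vx <- config$speed * d[1L] * ifelse(first, 1, -1)
    vy <- config$speed * d[2L] * ifelse(first, 1, -1)
  } else { # focal_heterogeneous
    src <- config$source_position
    het <- config$heterogeneity
    set.seed(config$seed)
    cs <- rnorm(het$n_regions, het$cv_mean, het$cv_sd)
    while (any(cs < het$cv_floor))
      cs[cs < het$cv_floor] <- rnorm(sum(cs < het$cv_floor),
                                     het$cv_mean, het$cv_sd)
    ang <- atan2(Y - src[2L], X - src[1L]) %% (2 * pi)
    sector <- pmin(floor(ang / (2 * pi / het$n_regions)) + 1L, het$n_regions)
    speed_map <- matrix(cs[sector], n, n)
    Fm <- cm_s_to_mm_ms(speed_map)
    # factored marching: T = u * T0 with T0 the homogeneous reference time,
    # seeded analytically (u = c0 / c) in a small disk around the source
    c0 <- cm_s_to_mm_ms(het$cv_mean)
    r <- sqrt((X - src[1L])^2 + (Y - src[2L])^2)
    T0 <- r / c0
    T0x <- ifelse(r > 0, (X - src[1L]) / r, 0) / c0
    T0y <- ifelse(r > 0, (Y - src[2L]) / r, 0) / c0
    u_init <- matrix(NA_real_, n, n)
    seedd <- r <= 3 * h
    u_init[seedd] <- c0 / Fm[seedd]
    times <- .fmm_factored(Fm, h, T0, T0x, T0y, u_init)
    g <- grid_gradient(times, h)            # ms/mm
    gn2 <- g$gx^2 + g$gy^2
    vx <- 100 * g$gx / gn2
    vy <- 100 * g$gy / gn2
  }

  if (config$time_quantum > 0)
    times <- round(times / config$time_quantum) * config$time_quantum

  structure(
    list(grid = list(x = gx, y = gy, h = h),
         times = times, vx = vx, vy = vy,
         speed_map = speed_map, source = src, config = config),
    class = "activation_field"
  )
}

# central finite-difference gradient of a grid field (one-sided at edges)
grid_gradient <- function(V, h) {
  n <- nrow(V); m <- ncol(V)
  gx <- V; gy <- V
  gx[2:(n - 1), ] <- (V[3:n, ] - V[1:(n - 2), ]) / (2 * h)
  gx[1, ] <- (V[2, ] - V[1, ]) / h
  gx[n, ] <- (V[n, ] - V[n - 1, ]) / h
  gy[, 2:(m - 1)] <- (V[, 3:m] - V[, 1:(m - 2)]) / (2 * h)
  gy[, 1] <- (V[, 2] - V[, 1]) / h
  gy[, m] <- (V[, m] - V[, m - 1]) / h
  list(gx = gx, gy = gy)
}

#' @export
print.activation_field <- function(x, ...) {
  cat(sprintf("<activation_field> %s, %d x %d grid (%.3g mm cells)\n",
              x$config$pattern, length(x$grid$x), length(x$grid$y), x$grid$h))
  invisible(x)
}

#' Sample an activation field through a placed catheter
#'
#' Bilinearly interpolates the field's activation times at the placed
#' layout points and replicates them over beats (`beat b = base +
#' (b - 1) * cycle_length`).
#'
#' @param field an `activation_field`.
#' @param layout a `catheter_layout` (catheter-centered frame).
#' @param center catheter center on the patch (mm); default patch center.
#' @param rotation catheter rotation (radians).
#' @param n_beats number of beats.
#' @param cycle_length cycle length (ms); defaults to the field config's.
#' @return a `multisite_recording`.
#' @export
sample_multisite <- function(field, layout, center = NULL, rotation = 0,
                             n_beats = 1L, cycle_length = NULL) {
  stopifnot(inherits(field, "activation_field"),
            inherits(layout, "catheter_layout"))
  ps <- field$config$patch_size
  center <- center %||% rep(ps / 2, 2L)
  cl <- cycle_length %||% field$config$cycle_length
  placed <- place_layout(layout, center, rotation)
  pts <- placed$points
  if (any(pts < 0) || any(pts > ps))
    stop_input("placed catheter points fall outside the patch")
  base <- bilinear_interp(field$grid$x, field$grid$y, field$times,
                          pts[, 1L], pts[, 2L])
  times <- outer(base, (seq_len(n_beats) - 1) * cl, `+`)
  multisite_recording(pts, times, cycle_length = cl, labels = placed$labels)
}

#' Add uniform activation-time jitter
#'
#' Adds independent uniform jitter to every non-missing activation time,
#' emulating annotation misdetections. The jitter amplitude
#' `eps = eps_fraction * cycle_length` is read as the full width of the
#' uniform distribution: with the default `"full_width"` convention the
#' jitter is drawn from `[-eps/2, +eps/2]` ms (the convention that
#' reproduces the package's stability benchmarks; see the methods
#' vignette), with `"half_width"` from `[-eps, +eps]`.
#'
#' @param recording a `multisite_recording`.
#' @param eps_fraction jitter amplitude as a fraction of cycle length, in
#'   `[0, 0.5]`.
#' @param seed RNG seed.
#' @param convention `"full_width"` (default) or `"half_width"`.
#' @return the jittered `multisite_recording`.
#' @export
add_jitter <- function(recording, eps_fraction, seed = 1L,
                       convention = c("full_width", "half_width")) {
  stopifnot(inherits(recording, "multisite_recording"))
  convention <- match.arg(convention)
  if (!is.numeric(eps_fraction) || eps_fraction < 0 || eps_fraction > 0.5)
    stop_input("eps_fraction must be in [0, 0.5]")
  if (eps_fraction == 0) return(recording)
  eps <- eps_fraction * recording$cycle_length
  if (convention == "full_width") eps <- eps / 2
  set.seed(seed)
  jit <- matrix(runif(length(recording$times), -eps, eps),
                nrow(recording$times), ncol(recording$times))
  jit[is.na(recording$times)] <- 0
  recording$times <- recording$times + jit
  recording
}

#' Remove randomly selected mapping sites
#'
#' Removes a uniform random subset of sites (the same sites for every
#' beat), emulating electrogram loss from poor contact.
#'
#' @param recording a `multisite_recording`.
#' @param n_remove number of sites to remove; at least 3 must remain.
#' @param seed RNG seed.
#' @return the reduced `multisite_recording`.
#' @export
remove_sites <- function(recording, n_remove, seed = 1L) {
  stopifnot(inherits(recording, "multisite_recording"))
  n <- nrow(recording$positions)
  if (n_remove < 0 || n - n_remove < 3L)
    stop_input("cannot remove ", n_remove, " of ", n,
               " sites: at least 3 must remain")
  if (n_remove == 0L) return(recording)
  set.seed(seed)
  drop_idx <- sample.int(n, n_remove)
  keep <- setdiff(seq_len(n), drop_idx)
  multisite_recording(recording$positions[keep, , drop = FALSE],
                      recording$times[keep, , drop = FALSE],
                      cycle_length = recording$cycle_length,
                      labels = recording$labels[keep])
}

#' Export an activation field as flat CSV
#'
#' One row per grid node: `x_mm`, `y_mm`, `t_ms`, `vx_cm_s`, `vy_cm_s`.
#'
#' @param field an `activation_field`.
#' @param path output CSV path.
#' @export
write_field_truth_csv <- function(field, path) {
  stopifnot(inherits(field, "activation_field"))
  n <- length(field$grid$x)
  df <- data.frame(
    x_mm = rep(field$grid$x, times = n),
    y_mm = rep(field$grid$y, each = n),
    t_ms = as.vector(field$times),
    vx_cm_s = as.vector(field$vx),
    vy_cm_s = as.vector(field$vy))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
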