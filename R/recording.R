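# Multisite recordings: site positions plus per-beat activation times.
# A missing activation is NA (never 0); beats are aligned per column.

#' Construct a multisite activation-time recording
#'
#' @param positions N x 2 matrix of site positions (mm).
#' @param times N x B matrix of activation times (ms), one column per beat;
#'   `NA` marks a missing activation. A vector is taken as a single beat.
#' @param cycle_length activation cycle length (ms).
#' @param labels optional per-site labels (default `S1..SN`).
#' @return a `multisite_recording`.
#' @export
multisite_recording <- function(positions, times, cycle_length = 150,
                                labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop_input("positions must be an N x 2 matrix")
  if (is.null(dim(times))) times <- matrix(times, ncol = 1L)
  times <- as.matrix(times)
  n <- nrow(positions)
  if (nrow(times) != n) stop_input("positions and times row counts differ")
  if (n < 3L) stop_input("at least 3 sites are required")
  if (any(is.infinite(times))) stop_input("times must be finite or NA")
  d <- stats::dist(positions)
  if (min(d) <= 1e-6)
    stop_input("duplicate site positions (separation <= 1e-6 mm)")
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  if (anyDuplicated(labels)) stop_input("site labels must be unique")
  storage.mode(positions) <- "double"
  storage.mode(times) <- "double"
  dimnames(positions) <- list(labels, c("x", "y"))
  dimnames(times) <- list(labels, NULL)
  structure(
    list(positions = positions, times = times,
         cycle_length = as.numeric(cycle_length),
         labels = as.character(labels)),
    class = "multisite_recording"
  )
}

#' @export
print.multisite_recording <- function(x, ...) {
  cat(sprintf("<multisite_recording> %d sites x %d beats, CL %.0f ms, %d missing\n",
              nrow(x$times), ncol(x$times), x$cycle_length, sum(is.na(x$times))))
  invisible(x)
}

#' Read / write a recording as CSV
#'
#' The CSV dialect has columns `label,x_mm,y_mm,t_beat1_ms,...,t_beatB_ms`;
#' an empty cell is a missing activation.
#'
#' @param path CSV file path.
#' @param cycle_length cycle length (ms) attached on read (not stored in the
#'   CSV).
#' @return `read_recording_csv` returns a `multisite_recording`;
#'   `write_recording_csv` returns `path` invisibly.
#' @export
read_recording_csv <- function(path, cycle_length = 150) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop_input("recording CSV must have columns label, x_mm, y_mm, t_beat*_ms")
  tcols <- grep("^t_beat[0-9]+_ms$", names(df), value = TRUE)
  if (length(tcols) == 0L) stop_input("no t_beat*_ms columns found")
  tcols <- tcols[order(as.integer(sub("^t_beat([0-9]+)_ms$", "\\1", tcols)))]
  xs <- suppressWarnings(as.numeric(df$x_mm))
  ys <- suppressWarnings(as.numeric(df$y_mm))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop_input("non-numeric or missing position in CSV row ", bad[1L])
  times <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, tcols, drop = FALSE])),
           nrow = nrow(df)))
  multisite_recording(cbind(df$x_mm, df$y_mm), times,
                      cycle_length = cycle_length, labels = df$label)
}

#' @rdname read_recording_csv
#' @param recording a `multisite_recording` to write.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "multisite_recording"))
  B <- ncol(recording$times)
  df <- data.frame(label = recording$labels,
                   x_mm = recording$positions[, 1L],
                   y_mm = recording$positions[, 2L])
  tm <- as.data.frame(recording$times)
  names(tm) <- paste0("t_beat", seq_len(B), "_ms")
  df <- cbind(df, tm)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
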