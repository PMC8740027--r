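# Multielectrode catheter layouts: the scattered sampling stencils used by
# the interpolation and simulation modules. All coordinates are in mm, in a
# catheter-centered frame (x right, y up) until a layout is placed on a
# tissue patch with place_layout().

new_catheter_layout <- function(points, labels, swept_radius) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_input("layout points must be an n x 2 matrix")
  if (nrow(points) < 3L) stop_input("a layout needs at least 3 points")
  if (anyDuplicated(labels)) stop_input("layout labels must be unique")
  if (length(labels) != nrow(points))
    stop_input("one label per point is required")
  sv <- svd(sweep(points, 2L, colMeans(points)))$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    stop_input("layout points must not be collinear")
  dimnames(points) <- list(labels, c("x", "y"))
  structure(
    list(points = points, labels = as.character(labels),
         swept_radius = as.numeric(swept_radius)),
    class = "catheter_layout"
  )
}

#' @export
print.catheter_layout <- function(x, ...) {
  cat(sprintf("<catheter_layout> %d points, swept radius %.3f mm\n",
              nrow(x$points), x$swept_radius))
  invisible(x)
}

# spline angles: five splines at 72 degree increments, spline A pointing up
pentaray_spline_angles <- function() (pi / 180) * (90 + 72 * 0:4)

pentaray_points <- function(radii) {
  ang <- pentaray_spline_angles()
  pts <- do.call(rbind, lapply(seq_along(ang), function(s) {
    cbind(radii * cos(ang[s]), radii * sin(ang[s]))
  }))
  labels <- as.vector(vapply(LETTERS[1:5], function(l) {
    paste0(l, "_", c("12", "23", "34"))
  }, character(3)))
  list(points = pts, labels = labels)
}

#' Fifteen-bipole five-spline mapping layout for tissue-patch studies
#'
#' Builds the 15-point sampling stencil emulating the bipole midpoints of a
#' five-spline (PentaRay-like) multipolar catheter: 5 splines at 72 degree
#' increments (spline A pointing along +y), 3 bipoles per spline at radii
#' proportional to 4, 8 and 12 mm, scaled so the outermost bipole sits at
#' `swept_radius`. Bipole labels follow the clinical convention
#' (`A_12` outermost through `A_34` innermost on each spline).
#'
#' The default swept radius is `2.7 / sqrt(0.05)` mm (about 12.07 mm), the
#' radius for which a disk of radius 2.7 mm covers 5% of the swept circular
#' area; see [localization_threshold()].
#'
#' @param swept_radius radius (mm) of the circular area swept by the catheter.
#' @return a `catheter_layout` with 15 labelled points.
#' @seealso [pentaray_bipole_layout_from_electrodes()], [place_layout()]
#' @export
#' @examples
#' lay <- pentaray_patch_layout()
#' max(sqrt(rowSums(lay$points^2)))  # = swept radius
pentaray_patch_layout <- function(swept_radius = 2.7 / sqrt(0.05)) {
  if (!is.numeric(swept_radius) || swept_radius <= 0)
    stop_input("swept_radius must be positive")
  radii <- c(12, 8, 4) * swept_radius / 12
  p <- pentaray_points(radii)
  new_catheter_layout(p$points, p$labels, swept_radius)
}

#' Bipole layout derived from a 20-electrode five-spline catheter
#'
#' Places 4 electrodes per spline at a given interelectrode spacing
#' (innermost electrode at half a spacing from the center, electrodes
#' numbered 1 to 4 from the distal/outer end inward) and reduces them to the
#' 15 midpoints of neighbouring electrode pairs on the same spline, the
#' positions attributed to bipolar electrograms.
#'
#' @param interelectrode_distance spacing between neighbouring electrodes on
#'   a spline, mm (clinical default 4 mm).
#' @return a `catheter_layout` with 15 bipole midpoints; `swept_radius` is
#'   the radius of the outermost electrode (3.5 spacings).
#' @export
#' @examples
#' lay <- pentaray_bipole_layout_from_electrodes(4)
#' sort(unique(round(sqrt(rowSums(lay$points^2)), 6)))  # 4, 8, 12 mm
pentaray_bipole_layout_from_electrodes <- function(interelectrode_distance = 4) {
  if (!is.numeric(interelectrode_distance) || interelectrode_distance <= 0)
    stop_input("interelectrode_distance must be positive")
  s <- interelectrode_distance
  # electrode radii s/2 + (0:3) s, outer to inner pairs -> midpoints 3s, 2s, s
  radii <- c(3, 2, 1) * s
  p <- pentaray_points(radii)
  new_catheter_layout(p$points, p$labels, swept_radius = 3.5 * s)
}

#' Rigidly place a catheter layout on the mapping plane
#'
#' Applies a rotation about the catheter center followed by a translation,
#' leaving all pairwise distances and the swept radius unchanged.
#'
#' @param layout a `catheter_layout`.
#' @param center length-2 numeric, new center position (mm).
#' @param rotation rotation angle (radians, counter-clockwise).
#' @return the transformed `catheter_layout`.
#' @export
place_layout <- function(layout, center = c(0, 0), rotation = 0) {
  stopifnot(inherits(layout, "catheter_layout"))
  pts <- layout$points %*% t(rot2(rotation))
  pts <- sweep(pts, 2L, as.numeric(center), `+`)
  dimnames(pts) <- dimnames(layout$points)
  layout$points <- pts
  layout
}

#' Serialize a catheter layout to JSON
#'
#' @param layout a `catheter_layout`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
layout_to_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "catheter_layout"))
  obj <- list(labels = layout$labels,
              points_mm = unname(layout$points),
              swept_radius_mm = layout$swept_radius)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
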