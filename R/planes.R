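#' Imaging plane in 3D
#'
#' A `slice_plane` is a 3D imaging plane carrying its own in-plane coordinate
#' frame, the atomic geometric object of a cine study.  Lengths are in mm
#' throughout.  The mapping `(u, v) -> origin + u * axis_u + v * axis_v` is an
#' isometry between plane coordinates and the lab frame.
#'
#' @param origin numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3, plane normal (normalized internally).
#' @param axis_u,axis_v in-plane unit vectors; if missing, an orthonormal
#'   in-plane frame is constructed deterministically from the normal.
#' @param slice_label one of `"SAX"`, `"LAX_2CH"`, `"LAX_4CH"`.
#' @param sax_index integer position of a SAX slice, base to apex; `NA` for
#'   long-axis slices.
#' @return an object of class `slice_plane`.
#' @export
slice_plane <- function(origin, normal, axis_u = NULL, axis_v = NULL,
                        slice_label = "SAX", sax_index = NA_integer_) {
  origin <- as.numeric(origin)
  normal <- as.numeric(normal)
  stopifnot(length(origin) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("slice_plane: zero-length normal")
  normal <- normal / nn
  if (is.null(axis_u)) {
    # deterministic in-plane frame: cross normal with the least-aligned lab axis
    ref <- diag(3)[, which.min(abs(normal))]
    axis_u <- vcross(ref, normal)
    axis_u <- axis_u / sqrt(sum(axis_u^2))
  } else {
    axis_u <- as.numeric(axis_u)
    axis_u <- axis_u / sqrt(sum(axis_u^2))
  }
  if (is.null(axis_v)) {
    axis_v <- vcross(normal, axis_u)
  } else {
    axis_v <- as.numeric(axis_v)
    axis_v <- axis_v / sqrt(sum(axis_v^2))
  }
  p <- structure(
    list(origin = origin, normal = normal, axis_u = axis_u, axis_v = axis_v,
         slice_label = match.arg(slice_label, c("SAX", "LAX_2CH", "LAX_4CH")),
         sax_index = as.integer(sax_index)),
    class = "slice_plane")
  validate_slice_plane(p)
  p
}

validate_slice_plane <- function(p, tol = 1e-9) {
  G <- rbind(p$normal, p$axis_u, p$axis_v)
  if (max(abs(G %*% t(G) - diag(3))) > tol)
    stop("slice_plane: normal, axis_u, axis_v are not orthonormal to tolerance ", tol)
  invisible(p)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert between plane and lab coordinates
#'
#' @param plane a [slice_plane()].
#' @param uv n x 2 matrix of in-plane coordinates (mm).
#' @param xyz n x 3 matrix of lab coordinates (mm).
#' @return `plane_to_world` gives an n x 3 matrix; `world_to_plane` an
#'   n x 2 matrix (the out-of-plane component is discarded).
#' @export
plane_to_world <- function(plane, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  sweep(uv %*% rbind(plane$axis_u, plane$axis_v), 2L, plane$origin, "+")
}

#' @rdname plane_to_world
#' @export
world_to_plane <- function(plane, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  d <- sweep(xyz, 2L, plane$origin)
  cbind(d %*% plane$axis_u, d %*% plane$axis_v)
}

#' Signed distance of points from a plane
#' @inheritParams plane_to_world
#' @return numeric vector, positive on the side the normal points to.
#' @export
plane_distance <- function(plane, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  drop(sweep(xyz, 2L, plane$origin) %*% plane$normal)
}

#' Total-least-squares plane through a point cloud
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' given points (orthogonal-distance regression): the plane passes through the
#' centroid with normal given by the smallest principal direction of the
#' centered cloud.  Used for the mitral-valve plane, defined each frame as the
#' 3D plane best fitting the four valve landmarks from the two long-axis views.
#'
#' Coincident points are collapsed before fitting; at least 3 distinct,
#' non-collinear points must remain.
#'
#' @param points n x 3 matrix (n >= 3) of 3D points (mm).
#' @param apex_hint optional 3D point; if given, the normal is oriented so that
#'   it points from the plane toward this point (toward the apex).
#' @param frame optional integer frame index carried through.
#' @return an object of class `mv_plane`: a list with `plane` (a
#'   [slice_plane()]), `source_points`, `rss` (residual sum of squared
#'   distances) and `frame`.
#' @export
fit_plane <- function(points, apex_hint = NULL, frame = NA_integer_) {
  pts <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(pts) < 3L) stop("fit_plane: need at least 3 points, got ", nrow(pts))
  dup <- duplicated(round(pts, 9L))
  if (any(dup)) {
    pts_d <- pts[!dup, , drop = FALSE]
    if (nrow(pts_d) < 3L)
      stop("fit_plane: degenerate geometry, fewer than 3 distinct points (",
           nrow(pts_d), " distinct of ", nrow(pts), ")")
  } else pts_d <- pts
  ctr <- colMeans(pts_d)
  X <- sweep(pts_d, 2L, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("fit_plane: degenerate geometry, points are collinear: ",
         paste(utils::capture.output(print(round(pts_d, 6))), collapse = " "))
  normal <- sv$v[, 3L]
  if (!is.null(apex_hint)) {
    if (sum((as.numeric(apex_hint) - ctr) * normal) < 0) normal <- -normal
  }
  rss <- sum((X %*% normal)^2)
  structure(
    list(plane = slice_plane(ctr, normal, slice_label = "SAX"),
         source_points = pts, rss = rss, frame = as.integer(frame)),
    class = "mv_plane")
}
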