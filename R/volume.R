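# Volume of the region bounded by a model surface and the mitral-valve (base)
# plane.  The surfaces are star-shaped about the model centre, so the region
# below the base plane is the set of points whose distance from the centre
# along direction e is below min(lambda(e), ray-plane distance).  The volume
# is the spherical-coordinate integral of bound^3 / 3 over directions; for
# each circumferential node the cut angle phi*(theta) where the surface meets
# the plane is located by root finding, and the longitudinal integral is done
# by composite Gauss-Legendre on each smooth piece.

gauss_segment <- function(f, lo, hi, order, n_seg = 2L) {
  if (hi <= lo) return(0)
  brk <- seq(lo, hi, length.out = n_seg + 1L)
  tot <- 0
  for (s in seq_len(n_seg)) {
    gl <- pracma::gaussLegendre(order, brk[s], brk[s + 1L])
    tot <- tot + sum(gl$w * f(gl$x))
  }
  tot
}

# signed quantities of a base plane relative to a model centre
base_geometry <- function(model, base) {
  plane <- if (inherits(base, "mv_plane")) base$plane else base
  n <- plane$normal
  # orient the normal toward the apex
  if (sum(n * model$axis_direction) < 0) n <- -n
  alpha_c <- sum((model$axis_origin - plane$origin) * n)
  if (alpha_c < -1e-9)
    stop("enclosed_volume: model centre lies on the basal side of the base ",
         "plane; the plane must truncate the surface above the centre")
  list(normal = n, alpha_c = max(alpha_c, 0), origin = plane$origin)
}

#' Volume enclosed by a surface up to the base plane
#'
#' Computes the volume (in microlitres = mm^3) of the region bounded by the
#' chosen surface of the model and, if given, the mitral-valve plane, by
#' numerical quadrature in the model's spherical parameterization.  The plane
#' must intersect the surface in a single closed curve encircling the long
#' axis, with the model centre on the apical side.
#'
#' @param model an [lv_surface_model()].
#' @param surface `"endo"` or `"epi"`.
#' @param base a [fit_plane()] result or [slice_plane()] truncating the
#'   surface basally; `NULL` integrates the full closed surface.
#' @param quadrature_order Gauss-Legendre order per longitudinal segment;
#'   circumferential integration uses `max(32, 4 * quadrature_order)`
#'   equispaced nodes (spectrally accurate for periodic integrands).
#' @return volume in microlitres.
#' @export
enclosed_volume <- function(model, surface = c("endo", "epi"), base = NULL,
                            quadrature_order = 8L) {
  surface <- match.arg(surface)
  order <- as.integer(quadrature_order)
  n_th <- max(32L, 4L * order)
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
  w_th <- 2 * pi / n_th
  b <- -model$axis_direction

  lam_at <- function(phi, theta)
    surface_lambda(model, surface, phi / pi, rep_len(theta, length(phi)))

  if (is.null(base)) {
    vals <- vapply(th, function(t)
      gauss_segment(function(phi) lam_at(phi, t)^3 / 3 * sin(phi),
                    0, pi, order, n_seg = 4L), 0)
    return(sum(vals) * w_th)
  }

  bg <- base_geometry(model, base)
  nrm <- bg$normal; alpha_c <- bg$alpha_c
  # e(phi, theta) . n decomposed
  cn <- sum(b * nrm)
  un <- sum(model$axis_u * nrm); vn <- sum(model$axis_v * nrm)
  en_of <- function(phi, tv) cos(phi) * cn + sin(phi) * (cos(tv) * un +
                                                           sin(tv) * vn)
  H_of <- function(phi, tv)
    alpha_c + surface_lambda(model, surface, phi / pi, tv) * en_of(phi, tv)

  # locate the cut angle phi*(theta) on all meridians at once: a coarse scan
  # to verify a single crossing, then vectorized bisection
  phi_grid <- seq(0, pi, length.out = 65L)
  hg <- matrix(H_of(rep(phi_grid, times = n_th),
                    rep(th, each = length(phi_grid))),
               length(phi_grid), n_th)
  flips <- colSums(hg[-1L, , drop = FALSE] * hg[-nrow(hg), , drop = FALSE] < 0)
  if (any(flips == 0L)) {
    if (all(hg > 0))
      stop("enclosed_volume: base plane does not cut the surface")
    stop("enclosed_volume: base plane misses the surface along some ",
         "meridians; intersection curve does not encircle the axis")
  }
  if (any(flips > 1L))
    stop("enclosed_volume: base plane cuts the surface more than once ",
         "along a meridian; expected a single closed intersection curve")
  first_flip <- apply(hg[-1L, , drop = FALSE] *
                        hg[-nrow(hg), , drop = FALSE] < 0, 2L, which.max)
  lo <- phi_grid[first_flip]; hi <- phi_grid[first_flip + 1L]
  for (i in seq_len(48L)) {
    mid <- (lo + hi) / 2
    neg <- H_of(mid, th) < 0
    lo <- ifelse(neg, mid, lo); hi <- ifelse(neg, hi, mid)
  }
  phi_star <- (lo + hi) / 2

  # composite Gauss-Legendre on [0, phi*] (planar cap) and [phi*, pi]
  # (surface body), nodes mapped per meridian
  gl <- pracma::gaussLegendre(order, 0, 1)
  seg_nodes <- function(a_vec, b_vec, n_seg) {
    brk <- lapply(seq_len(n_seg), function(s)
      cbind(a_vec + (b_vec - a_vec) * (s - 1L) / n_seg,
            a_vec + (b_vec - a_vec) * s / n_seg))
    nodes <- lapply(brk, function(ab)
      outer(ab[, 2L] - ab[, 1L], gl$x) + ab[, 1L])   # n_th x order
    wts <- lapply(brk, function(ab) outer(ab[, 2L] - ab[, 1L], gl$w))
    list(x = do.call(cbind, nodes), w = do.call(cbind, wts))
  }
  cap_n <- seg_nodes(rep(0, n_th), phi_star, 2L)
  thm_cap <- matrix(th, n_th, ncol(cap_n$x))
  cap_f <- (-alpha_c / en_of(cap_n$x, thm_cap))^3 / 3 * sin(cap_n$x)
  body_n <- seg_nodes(phi_star, rep(pi, n_th), 3L)
  thm_b <- matrix(th, n_th, ncol(body_n$x))
  body_f <- matrix(surface_lambda(model, surface, as.vector(body_n$x) / pi,
                                  as.vector(thm_b)),
                   n_th)^3 / 3 * sin(body_n$x)
  sum(cap_f * cap_n$w, body_f * body_n$w) * w_th
}

#' Intersect a surface with an imaging plane
#'
#' Returns the closed intersection curve of the chosen surface with a plane,
#' as an ordered counter-clockwise polygon in the plane's `(u, v)`
#' coordinates.  Two geometric situations are handled: a plane through the
#' model centre (long-axis views) is sampled star-wise in-plane, and a plane
#' separating the two poles (short-axis views) is traced by root finding
#' along meridians.  A plane that misses or merely grazes the surface yields
#' an empty contour flagged degenerate rather than an error.
#'
#' @param model an [lv_surface_model()].
#' @param surface `"endo"` or `"epi"`.
#' @param plane a [slice_plane()].
#' @param n_points number of contour points.
#' @return list with `uv` (n x 2 matrix, counter-clockwise, possibly 0-row),
#'   `xyz` (n x 3), and `degenerate` flag.
#' @export
intersect_surface_with_plane <- function(model, surface = c("endo", "epi"),
                                         plane, n_points = 64L) {
  surface <- match.arg(surface)
  ctr <- model$axis_origin
  dc <- sum((ctr - plane$origin) * plane$normal)
  empty <- list(uv = matrix(numeric(0), 0L, 2L),
                xyz = matrix(numeric(0), 0L, 3L), degenerate = TRUE)

  if (abs(dc) < 1e-9) {
    # plane through the centre: star-shaped section about the centre
    psi <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    e <- outer(cos(psi), plane$axis_u) + outer(sin(psi), plane$axis_v)
    prm <- point_to_param(model, sweep(e, 2L, ctr, "+"))
    r <- surface_lambda(model, surface, prm[, "mu"], prm[, "theta"])
    xyz <- sweep(e * r, 2L, ctr, "+")
  } else {
    pole_base <- surface_point(model, surface, 0, 0)
    pole_apex <- surface_point(model, surface, 1, 0)
    s0 <- plane_distance(plane, pole_base); s1 <- plane_distance(plane, pole_apex)
    if (s0 * s1 >= 0) {
      # poles on the same side: no curve encircling the axis
      return(empty)
    }
    th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    f_of <- function(mu, tv) {
      lam <- surface_lambda(model, surface, mu, tv)
      e <- radial_direction(model, mu, tv)
      drop(sweep(e * lam, 2L, ctr - plane$origin, "+") %*% plane$normal)
    }
    neg_at_0 <- s0 < 0
    lo <- rep(0, n_points); hi <- rep(1, n_points)
    for (i in seq_len(52L)) {
      mid <- (lo + hi) / 2
      low_side <- (f_of(mid, th) < 0) == neg_at_0
      lo <- ifelse(low_side, mid, lo); hi <- ifelse(low_side, hi, mid)
    }
    mu_star <- (lo + hi) / 2
    xyz <- surface_point(model, surface, mu_star, th)
  }
  uv <- world_to_plane(plane, xyz)
  # orient counter-clockwise in (u, v)
  a2 <- sum(uv[, 1L] * c(uv[-1L, 2L], uv[1L, 2L]) -
              c(uv[-1L, 1L], uv[1L, 1L]) * uv[, 2L])
  if (a2 < 0) { uv <- uv[rev(seq_len(nrow(uv))), ]; xyz <- xyz[rev(seq_len(nrow(xyz))), ] }
  list(uv = uv, xyz = xyz, degenerate = FALSE)
}

#' Volume by voxel counting
#'
#' Independent volumetric oracle: counts voxel centres of an axis-aligned
#' 3D grid falling inside the surface (and on the apical side of the base
#' plane, if given) and multiplies by the voxel volume.  Shares no
#' integration machinery with [enclosed_volume()].
#'
#' @inheritParams enclosed_volume
#' @param voxel_mm voxel edge length (mm); 0.02 mm matches the oracle
#'   resolution used for phantom ground truth.
#' @param lambda_fn optional analytic radial field `(mu, theta) -> mm`
#'   overriding the model's basis representation, so analytic phantom
#'   surfaces can be voxelized directly.
#' @return volume in microlitres.
#' @export
voxelized_volume <- function(model, surface = c("endo", "epi"), base = NULL,
                             voxel_mm = 0.02, lambda_fn = NULL) {
  surface <- match.arg(surface)
  ctr <- model$axis_origin
  g <- expand.grid(mu = seq(0, 1, length.out = 64L),
                   th = seq(0, 2 * pi, length.out = 65L)[-65L])
  lam_of <- if (is.null(lambda_fn))
    function(mu, th) surface_lambda(model, surface, mu, th) else lambda_fn
  # dense bilinear lookup of the radial field (interpolation error far below
  # the voxel discretization error)
  n_mu <- 1024L; n_th <- 1024L
  mu_g <- seq(0, 1, length.out = n_mu + 1L)
  th_g <- seq(0, 2 * pi, length.out = n_th + 1L)
  L <- matrix(lam_of(rep(mu_g, times = n_th + 1L),
                     rep(th_g, each = n_mu + 1L)), n_mu + 1L, n_th + 1L)
  lam_interp <- function(mu, th) {
    fi <- pmin(pmax(mu, 0), 1) * n_mu
    fj <- (th %% (2 * pi)) / (2 * pi) * n_th
    i <- pmin(floor(fi), n_mu - 1L); j <- pmin(floor(fj), n_th - 1L)
    di <- fi - i; dj <- fj - j
    i <- i + 1L; j <- j + 1L
    L[cbind(i, j)] * (1 - di) * (1 - dj) + L[cbind(i + 1L, j)] * di * (1 - dj) +
      L[cbind(i, j + 1L)] * (1 - di) * dj + L[cbind(i + 1L, j + 1L)] * di * dj
  }
  lam_max <- max(L) * 1.001
  if (!is.null(base)) bg <- base_geometry(model, base)
  r <- lam_max + voxel_mm
  ax <- seq(ctr[1L] - r, ctr[1L] + r, by = voxel_mm)
  ay <- seq(ctr[2L] - r, ctr[2L] + r, by = voxel_mm)
  az <- seq(ctr[3L] - r, ctr[3L] + r, by = voxel_mm)
  xy <- as.matrix(expand.grid(x = ax, y = ay))
  count <- 0
  for (z in az) {
    pts <- cbind(xy, z)
    keep <- rowSums(sweep(pts, 2L, ctr)^2) <= lam_max^2
    if (!is.null(base))
      keep <- keep & drop(sweep(pts, 2L, bg$origin) %*% bg$normal) >= 0
    if (!any(keep)) next
    pts <- pts[keep, , drop = FALSE]
    prm <- point_to_param(model, pts)
    count <- count + sum(prm[, "r"] <= lam_interp(prm[, "mu"], prm[, "theta"]))
  }
  count * voxel_mm^3
}
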