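# Parametric LV surface pair: a radial field lambda(mu, theta) per surface
# about a long-axis-aligned centre, expanded in clamped cubic B-splines in mu
# (pole rows tied so both poles close to a single point) x periodic cubic
# B-splines in theta.  mu = 0 is the base pole, mu = 1 the apex; the polar
# angle is phi = pi * mu measured from the base direction.

#' Clamped cubic B-spline basis on [0, 1]
#' @param x evaluation points in [0, 1].
#' @param k number of basis functions (>= 4).
#' @param deriv derivative order (0, 1 or 2).
#' @return length(x) x k design matrix.
#' @keywords internal
mu_basis <- function(x, k, deriv = 0L) {
  stopifnot(k >= 4L)
  knots <- c(rep(0, 4L), seq_len(k - 4L) / (k - 3L), rep(1, 4L))
  splines::splineDesign(knots, x, ord = 4L, derivs = rep(deriv, length(x)))
}

#' Periodic cubic B-spline basis on [0, 2*pi)
#' @inheritParams mu_basis
#' @return length(x) x k design matrix; columns are 2*pi-periodic.
#' @keywords internal
theta_basis <- function(x, k, deriv = 0L) {
  stopifnot(k >= 4L)
  h <- 2 * pi / k
  x <- x %% (2 * pi)
  knots <- seq(-3L, k + 3L) * h
  D <- splines::splineDesign(knots, x, ord = 4L, derivs = rep(deriv, length(x)),
                             outer.ok = TRUE)
  out <- matrix(0, nrow(D), k)
  for (j in seq_len(ncol(D))) {
    jj <- ((j - 1L) %% k) + 1L
    out[, jj] <- out[, jj] + D[, j]
  }
  out
}

# Reduced (pole-tied) design matrix.  Coefficient layout:
#   p[1]                      base-pole value (shared across theta)
#   p[2 .. 1+(k_mu-2)*k_th]   interior rows, theta index fastest
#   p[m]                      apex value
# Partition of unity of the periodic basis makes the pole columns
# sum(P_theta) * B_mu[, pole]; for theta-derivatives that sum vanishes.
reduced_design <- function(mu, theta, k_mu, k_th, dmu = 0L, dth = 0L) {
  B <- mu_basis(mu, k_mu, deriv = dmu)
  P <- theta_basis(theta, k_th, deriv = dth)
  mid <- B[, rep(2:(k_mu - 1L), each = k_th), drop = FALSE] *
    P[, rep(seq_len(k_th), k_mu - 2L), drop = FALSE]
  rs <- rowSums(P)
  cbind(B[, 1L] * rs, mid, B[, k_mu] * rs, deparse.level = 0)
}

n_reduced <- function(k_mu, k_th) 2L + (k_mu - 2L) * k_th

# expand reduced coefficient vector to the full k_mu x k_th grid
coef_to_grid <- function(p, k_mu, k_th) {
  g <- matrix(0, k_mu, k_th)
  g[1L, ] <- p[1L]
  g[k_mu, ] <- p[length(p)]
  g[2:(k_mu - 1L), ] <- matrix(p[2:(length(p) - 1L)], k_mu - 2L, k_th,
                               byrow = TRUE)
  g
}

grid_to_coef <- function(g) {
  k_mu <- nrow(g)
  c(g[1L, 1L], as.vector(t(g[2:(k_mu - 1L), , drop = FALSE])), g[k_mu, 1L])
}

#' Construct an LV surface model
#'
#' The model holds one radial field per surface (endocardial and epicardial),
#' each a tensor-product B-spline expansion of the radius lambda (mm) as a
#' function of longitudinal parameter `mu` in `[0, 1]` (0 = base pole, 1 =
#' apex) and circumferential angle `theta` in `[0, 2*pi)`, measured about the
#' LV long axis.  Pole rows of the coefficient grids are tied so each surface
#' closes to a single well-defined point at both poles; the periodic basis in
#' theta makes value and derivative match at theta = 0 and 2*pi.
#'
#' @param axis_origin centre of the radial field (mm, lab frame).
#' @param axis_direction unit vector along the long axis, pointing base to
#'   apex.
#' @param axis_u,axis_v unit vectors completing a right-handed frame with the
#'   axis; `theta = 0` points along `axis_u`.
#' @param coeffs_endo,coeffs_epi coefficient grids, `basis_order[1]` x
#'   `basis_order[2]`; pole rows (first and last) must be constant.
#' @param basis_order integer pair `(n_mu, n_theta)`.
#' @param focal_length characteristic long-axis half-length (mm), recorded for
#'   reference.
#' @return an object of class `lv_surface_model`.
#' @export
lv_surface_model <- function(axis_origin, axis_direction, axis_u = NULL,
                             axis_v = NULL, coeffs_endo, coeffs_epi,
                             basis_order = c(6L, 8L), focal_length = NA_real_) {
  d <- as.numeric(axis_direction); d <- d / sqrt(sum(d^2))
  if (is.null(axis_u)) {
    ref <- diag(3)[, which.min(abs(d))]
    axis_u <- vcross(ref, d); axis_u <- axis_u / sqrt(sum(axis_u^2))
  }
  if (is.null(axis_v)) axis_v <- vcross(d, axis_u)
  k_mu <- as.integer(basis_order[1L]); k_th <- as.integer(basis_order[2L])
  ce <- as.matrix(coeffs_endo); cp <- as.matrix(coeffs_epi)
  stopifnot(all(dim(ce) == c(k_mu, k_th)), all(dim(cp) == c(k_mu, k_th)))
  # enforce pole closure exactly
  ce[1L, ] <- mean(ce[1L, ]); ce[k_mu, ] <- mean(ce[k_mu, ])
  cp[1L, ] <- mean(cp[1L, ]); cp[k_mu, ] <- mean(cp[k_mu, ])
  structure(
    list(axis_origin = as.numeric(axis_origin), axis_direction = d,
         axis_u = as.numeric(axis_u), axis_v = as.numeric(axis_v),
         coeffs_endo = ce, coeffs_epi = cp,
         basis_order = c(k_mu, k_th), focal_length = focal_length),
    class = "lv_surface_model")
}

surface_coeffs <- function(model, surface = c("endo", "epi")) {
  switch(match.arg(surface), endo = model$coeffs_endo, epi = model$coeffs_epi)
}

#' Evaluate the radial field of a surface
#'
#' @param model an [lv_surface_model()].
#' @param surface `"endo"` or `"epi"`.
#' @param mu,theta parameter vectors (recycled to common length); `mu` in
#'   `[0, 1]`, `theta` any angle (wrapped).
#' @param dmu,dth derivative orders with respect to `mu` and `theta`.
#' @return numeric vector of radii lambda (mm), or parametric derivatives.
#' @export
surface_lambda <- function(model, surface = c("endo", "epi"), mu, theta,
                           dmu = 0L, dth = 0L) {
  if (any(mu < -1e-12 | mu > 1 + 1e-12))
    stop("surface_lambda: mu outside [0, 1]")
  mu <- pmin(pmax(mu, 0), 1)
  n <- max(length(mu), length(theta))
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  C <- surface_coeffs(model, surface)
  B <- mu_basis(mu, model$basis_order[1L], deriv = dmu)
  P <- theta_basis(theta, model$basis_order[2L], deriv = dth)
  rowSums((B %*% C) * P)
}

# unit radial directions e(mu, theta) in the lab frame (n x 3)
radial_direction <- function(model, mu, theta) {
  n <- max(length(mu), length(theta))
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  phi <- pi * mu
  b <- -model$axis_direction   # toward the base
  outer(cos(phi), b) +
    outer(sin(phi) * cos(theta), model$axis_u) +
    outer(sin(phi) * sin(theta), model$axis_v)
}

#' Evaluate surface points in 3D
#'
#' @inheritParams surface_lambda
#' @return n x 3 matrix of lab-frame points (mm).
#' @export
surface_point <- function(model, surface = c("endo", "epi"), mu, theta) {
  surface <- match.arg(surface)
  lam <- surface_lambda(model, surface, mu, theta)
  if (any(!is.finite(lam))) stop("surface_point: non-finite radius")
  e <- radial_direction(model, mu, theta)
  sweep(e * lam, 2L, model$axis_origin, "+")
}

# map lab-frame points to (mu, theta, r) radial coordinates about the model axis
point_to_param <- function(model, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  d <- sweep(xyz, 2L, model$axis_origin)
  r <- sqrt(rowSums(d^2))
  e <- d / pmax(r, 1e-300)
  cb <- drop(e %*% (-model$axis_direction))
  phi <- acos(pmin(pmax(cb, -1), 1))
  theta <- atan2(drop(e %*% model$axis_v), drop(e %*% model$axis_u)) %% (2 * pi)
  cbind(mu = phi / pi, theta = theta, r = r)
}

#' Validate an LV surface model
#'
#' Checks that both radial fields are strictly positive and that the
#' epicardial field dominates the endocardial field on a sampling grid.
#'
#' @param model an [lv_surface_model()].
#' @param n_grid grid resolution per parameter.
#' @return the model, invisibly; errors describe the violated invariant.
#' @export
validate_lv_surface_model <- function(model, n_grid = 64L) {
  mu <- seq(0, 1, length.out = n_grid)
  th <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  g <- expand.grid(mu = mu, th = th)
  le <- surface_lambda(model, "endo", g$mu, g$th)
  lp <- surface_lambda(model, "epi", g$mu, g$th)
  if (any(le <= 0) || any(lp <= 0))
    stop("lv_surface_model: radial field not strictly positive")
  if (any(lp < le - 1e-9))
    stop("lv_surface_model: epicardial surface crosses inside endocardial ",
         "surface (max crossing ", signif(max(le - lp), 3), " mm)")
  invisible(model)
}

#' Build a model whose radial fields match given functions
#'
#' Projects analytic radial fields onto the tensor B-spline basis by least
#' squares on a dense parameter grid (with pole tying), giving a
#' basis-represented model that reproduces the functions to interpolation
#' accuracy.  Used by the phantom generator and for analytic test surfaces.
#'
#' @param lambda_endo,lambda_epi functions of `(mu, theta)` returning radii
#'   (mm), vectorized.
#' @param basis_order integer pair `(n_mu, n_theta)`.
#' @inheritParams lv_surface_model
#' @return an [lv_surface_model()].
#' @export
model_from_lambda <- function(lambda_endo, lambda_epi, axis_origin = c(0, 0, 0),
                              axis_direction = c(0, 0, -1), axis_u = NULL,
                              axis_v = NULL, basis_order = c(12L, 16L),
                              focal_length = NA_real_) {
  k_mu <- as.integer(basis_order[1L]); k_th <- as.integer(basis_order[2L])
  mu <- seq(0, 1, length.out = max(4L * k_mu, 48L))
  th <- seq(0, 2 * pi, length.out = max(4L * k_th, 48L) + 1L)
  th <- th[-length(th)]
  g <- expand.grid(mu = mu, th = th)
  A <- reduced_design(g$mu, g$th, k_mu, k_th)
  fit_one <- function(f) {
    y <- f(g$mu, g$th)
    qr.coef(qr(A), y)
  }
  pe <- fit_one(lambda_endo); pp <- fit_one(lambda_epi)
  lv_surface_model(axis_origin, axis_direction, axis_u, axis_v,
                   coef_to_grid(pe, k_mu, k_th), coef_to_grid(pp, k_mu, k_th),
                   basis_order = c(k_mu, k_th), focal_length = focal_length)
}

#' Radial field of an axis-aligned ellipsoid
#'
#' Closed-form radius of an ellipsoid with semi-axes `(a, b, c)` (mm) about its
#' centre, `c` along the long axis, as a function of the model parameters.
#'
#' @param a,b,c semi-axes (mm); `a` along `theta = 0`, `c` along the long axis.
#' @return a vectorized function of `(mu, theta)`.
#' @export
ellipsoid_lambda <- function(a, b, c) {
  force(a); force(b); force(c)
  function(mu, theta) {
    phi <- pi * mu
    s <- sin(phi)
    1 / sqrt((s * cos(theta) / a)^2 + (s * sin(theta) / b)^2 +
               (cos(phi) / c)^2)
  }
}

#' Uniformly scale a model
#' @param model an [lv_surface_model()].
#' @param s scale factor applied to both radial fields about the axis origin.
#' @return the scaled model.
#' @export
scale_model <- function(model, s) {
  model$coeffs_endo <- model$coeffs_endo * s
  model$coeffs_epi <- model$coeffs_epi * s
  model
}
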