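# Parametric beating mouse-LV phantom.  Surfaces are truncated-ellipsoid
# radial fields with a raised-cosine systolic time course; an optional
# infarct adds a radial bulge, wall thinning and frozen (akinetic) motion
# inside a smooth parameter window.  All ground-truth volumes have closed
# forms or are computed by high-order quadrature on the analytic fields.

#' Volume of an ellipsoid truncated by a plane normal to its long axis
#'
#' Closed-form volume of the region of an axis-aligned ellipsoid with
#' semi-axes `(a, b, c)` below the plane at height `h` above the centre
#' (along the `c` axis).
#'
#' @param a,b,c semi-axes (mm).
#' @param h truncation height above the centre (mm); `h >= c` gives the full
#'   ellipsoid.
#' @return volume in microlitres.
#' @export
truncated_ellipsoid_volume <- function(a, b, c, h) {
  if (h >= c) return(4 / 3 * pi * a * b * c)
  if (h <= -c) return(0)
  pi * a * b * (h + 2 * c / 3 - h^3 / (3 * c^2))
}

#' Specification of a beating-LV phantom
#'
#' @param endo_semi_axes_ed end-diastolic endocardial semi-axes `(a, b, c)`
#'   in mm, `c` along the long axis.
#' @param wall_thickness_ed end-diastolic wall thickness (mm), applied as a
#'   uniform offset to the semi-axes.
#' @param base_truncation_fraction fraction of `c` above the centre at which
#'   the basal (mitral-valve) plane sits.
#' @param n_frames number of cine frames over the cycle.
#' @param contraction_fraction peak fractional reduction of the endocardial
#'   short semi-axes at end-systole, in (0, 1).
#' @param long_axis_contraction_fraction peak fractional reduction of the
#'   endocardial long semi-axis (base-apex shortening), in [0, 1).
#' @param infarct optional list with `center_theta` (rad), `center_mu`
#'   ([0,1]), `angular_halfwidth` (rad), `mu_halfwidth`, `wall_thinning_fraction`
#'   ([0,1)), `bulge_mm` (>= 0) and `akinetic` (logical).
#' @param noise_sd_mm in-plane contour noise SD used by [acquire_study()].
#' @param rng_seed integer seed for acquisition noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(endo_semi_axes_ed = c(1.95, 1.95, 4.6),
                         wall_thickness_ed = 1.0,
                         base_truncation_fraction = 0.55,
                         n_frames = 20L,
                         contraction_fraction = 0.35,
                         long_axis_contraction_fraction = 0.05,
                         infarct = NULL,
                         noise_sd_mm = 0.02,
                         rng_seed = 1L) {
  spec <- list(endo_semi_axes_ed = as.numeric(endo_semi_axes_ed),
               wall_thickness_ed = wall_thickness_ed,
               base_truncation_fraction = base_truncation_fraction,
               n_frames = as.integer(n_frames),
               contraction_fraction = contraction_fraction,
               long_axis_contraction_fraction = long_axis_contraction_fraction,
               infarct = infarct,
               noise_sd_mm = noise_sd_mm,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  bad <- character(0)
  if (length(spec$endo_semi_axes_ed) != 3L || any(spec$endo_semi_axes_ed <= 0))
    bad <- c(bad, "endo_semi_axes_ed")
  if (spec$wall_thickness_ed <= 0) bad <- c(bad, "wall_thickness_ed")
  if (spec$base_truncation_fraction <= 0 || spec$base_truncation_fraction >= 1)
    bad <- c(bad, "base_truncation_fraction")
  if (spec$n_frames < 2L) bad <- c(bad, "n_frames")
  if (spec$contraction_fraction < 0 || spec$contraction_fraction >= 1)
    bad <- c(bad, "contraction_fraction")
  if (spec$long_axis_contraction_fraction < 0 ||
      spec$long_axis_contraction_fraction >= 1)
    bad <- c(bad, "long_axis_contraction_fraction")
  if (spec$noise_sd_mm < 0) bad <- c(bad, "noise_sd_mm")
  if (!is.null(spec$infarct)) {
    inf <- spec$infarct
    need <- c("center_theta", "center_mu", "angular_halfwidth", "mu_halfwidth",
              "wall_thinning_fraction", "bulge_mm", "akinetic")
    if (!all(need %in% names(inf))) {
      bad <- c(bad, paste0("infarct$", setdiff(need, names(inf))))
    } else {
      if (inf$center_mu - inf$mu_halfwidth < 0 ||
          inf$center_mu + inf$mu_halfwidth > 1)
        bad <- c(bad, "infarct$mu_halfwidth (region leaves parameter domain)")
      if (inf$wall_thinning_fraction < 0 || inf$wall_thinning_fraction >= 1)
        bad <- c(bad, "infarct$wall_thinning_fraction")
      if (inf$bulge_mm < 0) bad <- c(bad, "infarct$bulge_mm")
      if (spec$wall_thickness_ed * (1 - inf$wall_thinning_fraction) <= 0.05)
        bad <- c(bad, "infarct$wall_thinning_fraction (wall below 0.05 mm)")
    }
  }
  if (length(bad))
    stop("phantom_spec: invalid fields: ", paste(bad, collapse = ", "))
  spec
}

#' Preset phantom specifications
#'
#' `"control"` emulates a healthy mouse LV (EDV near 64 ul, mass near
#' 105 mg, EF near 60%); `"infarct"` a chronically infarcted, dilated LV
#' (EDV near 162 ul, EF near 20%) with an akinetic, thinned, bulging
#' anterolateral region covering roughly 39% of the myocardium.
#'
#' @param preset `"control"` or `"infarct"`.
#' @param rng_seed acquisition noise seed.
#' @param infarct_extent_scale multiplies the infarct window's angular
#'   halfwidth (infarct preset only; the longitudinal halfwidth is bounded by
#'   the parameter domain), spanning akinetic fractions of roughly 35-48%
#'   over scales 0.9-1.25.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("control", "infarct"), rng_seed = 1L,
                           infarct_extent_scale = 1) {
  preset <- match.arg(preset)
  if (preset == "control") {
    phantom_spec(rng_seed = rng_seed)
  } else {
    phantom_spec(endo_semi_axes_ed = c(2.85, 2.85, 5.0),
                 wall_thickness_ed = 0.82,
                 contraction_fraction = 0.18,
                 long_axis_contraction_fraction = 0.03,
                 infarct = list(center_theta = 2.6, center_mu = 0.64,
                                angular_halfwidth = 2.3 * infarct_extent_scale,
                                mu_halfwidth = 0.34,
                                wall_thinning_fraction = 0.45,
                                bulge_mm = 0.35, akinetic = TRUE),
                 noise_sd_mm = 0.02, rng_seed = rng_seed)
  }
}

# plateau + raised-cosine taper window: 1 for |x| <= p, cosine down to 0 at 1
taper <- function(x, plateau = 0.6) {
  x <- abs(x)
  ifelse(x <= plateau, 1,
         ifelse(x >= 1, 0, 0.5 * (1 + cos(pi * (x - plateau) / (1 - plateau)))))
}

infarct_window <- function(infarct, mu, theta) {
  if (is.null(infarct)) return(rep(0, max(length(mu), length(theta))))
  dth <- atan2(sin(theta - infarct$center_theta),
               cos(theta - infarct$center_theta))
  taper(dth / infarct$angular_halfwidth) *
    taper((mu - infarct$center_mu) / infarct$mu_halfwidth)
}

# analytic per-frame radial fields for the phantom
phantom_fields <- function(spec) {
  a <- spec$endo_semi_axes_ed[1L]; b <- spec$endo_semi_axes_ed[2L]
  cc <- spec$endo_semi_axes_ed[3L]
  t0 <- spec$wall_thickness_ed
  h <- spec$base_truncation_fraction * cc
  gam <- spec$contraction_fraction; gam_l <- spec$long_axis_contraction_fraction
  a_e <- a + t0; c_e <- cc + t0
  f_epi <- (h + 2 * c_e / 3 - h^3 / (3 * c_e^2))
  v_endo_ed <- truncated_ellipsoid_volume(a, b, cc, h)
  myo_v <- truncated_ellipsoid_volume(a_e, a_e, c_e, h) - v_endo_ed
  g_of <- function(f) (1 - cos(2 * pi * (f - 1) / spec$n_frames)) / 2
  endo_healthy <- function(f) {
    g <- g_of(f)
    ellipsoid_lambda(a * (1 - gam * g), b * (1 - gam * g), cc * (1 - gam_l * g))
  }
  epi_healthy <- function(f) {
    g <- g_of(f)
    v_en <- truncated_ellipsoid_volume(a * (1 - gam * g), b * (1 - gam * g),
                                       cc * (1 - gam_l * g), h)
    ae_f <- sqrt((v_en + myo_v) / (pi * f_epi))
    ellipsoid_lambda(ae_f, ae_f, c_e)
  }
  inf <- spec$infarct
  endo_ed_h <- endo_healthy(1L); epi_ed_h <- epi_healthy(1L)
  lam_endo <- function(f) {
    eh <- endo_healthy(f)
    function(mu, theta) {
      w <- infarct_window(inf, mu, theta)
      ed_inf <- endo_ed_h(mu, theta) + if (is.null(inf)) 0 else inf$bulge_mm * w
      delta <- eh(mu, theta) - endo_ed_h(mu, theta)
      if (!is.null(inf) && isTRUE(inf$akinetic)) delta <- (1 - w) * delta
      ed_inf + delta
    }
  }
  lam_epi <- function(f) {
    ph <- epi_healthy(f)
    function(mu, theta) {
      w <- infarct_window(inf, mu, theta)
      wall_ed <- epi_ed_h(mu, theta) - endo_ed_h(mu, theta)
      thin <- if (is.null(inf)) 0 else inf$wall_thinning_fraction * w
      ed_inf <- endo_ed_h(mu, theta) +
        (if (is.null(inf)) 0 else inf$bulge_mm * w) + wall_ed * (1 - thin)
      delta <- ph(mu, theta) - epi_ed_h(mu, theta)
      if (!is.null(inf) && isTRUE(inf$akinetic)) delta <- (1 - w) * delta
      ed_inf + delta
    }
  }
  list(lam_endo = lam_endo, lam_epi = lam_epi, base_height = h,
       endo_healthy = endo_healthy)
}

# surface area integral of an indicator over the ED mid-wall below the base
# plane; lam/lam_dmu/lam_dth are functions of (mu, theta)
midwall_area_fraction <- function(lam, lam_dmu, lam_dth, base_height, mask_fn,
                                  n_mu = 256L, n_th = 256L) {
  mu <- seq(1e-4, 1 - 1e-4, length.out = n_mu)
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
  g <- expand.grid(mu = mu, th = th)
  lm <- lam(g$mu, g$th)
  dphi <- lam_dmu(g$mu, g$th) / pi
  dth <- lam_dth(g$mu, g$th)
  phi <- pi * g$mu
  dA <- lm * sqrt(lm^2 * sin(phi)^2 + dphi^2 * sin(phi)^2 + dth^2)
  in_lv <- lm * cos(phi) <= base_height
  ak <- mask_fn(g$mu, g$th) & in_lv
  100 * sum(dA[ak]) / sum(dA[in_lv])
}

numeric_dmu <- function(f, eps = 1e-5) function(mu, theta)
  (f(pmin(mu + eps, 1), theta) - f(pmax(mu - eps, 0), theta)) /
  (pmin(mu + eps, 1) - pmax(mu - eps, 0))
numeric_dth <- function(f, eps = 1e-5) function(mu, theta)
  (f(mu, theta + eps) - f(mu, theta - eps)) / (2 * eps)

#' Generate a beating-LV phantom with ground truth
#'
#' Builds per-frame surface models from the analytic phantom fields (frame 1
#' is end-diastole; the raised-cosine cycle puts end-systole at mid-cycle)
#' and computes ground-truth volumes by numerical integration of the fitted
#' fields up to the basal plane.  Truth mass is the mean of the end-diastolic
#' and end-systolic myocardial volumes times 1.05 mg/ul; the wall is
#' volume-conserving by construction, so the per-frame myocardial volume is
#' frame-invariant up to the infarct window's local remodelling.
#'
#' @param spec a [phantom_spec()].
#' @param truth_basis_order basis resolution of the truth surface models.
#' @param quadrature_order quadrature order for the truth volumes.
#' @return an object of class `truth_model`: per-frame
#'   [lv_surface_model()]s, the basal plane, `true_edv`, `true_esv`,
#'   `true_sv`, `true_ef` (fraction), `true_mass` (mg),
#'   `true_infarct_fraction` (%), `es_frame` and the analytic fields.
#' @export
make_phantom <- function(spec, truth_basis_order = c(12L, 16L),
                         quadrature_order = 10L) {
  validate_phantom_spec(spec)
  fld <- phantom_fields(spec)
  k_mu <- truth_basis_order[1L]; k_th <- truth_basis_order[2L]
  mu_g <- seq(0, 1, length.out = max(4L * k_mu, 48L))
  th_g <- seq(0, 2 * pi, length.out = max(4L * k_th, 64L) + 1L)
  th_g <- th_g[-length(th_g)]
  grd <- expand.grid(mu = mu_g, th = th_g)
  A <- reduced_design(grd$mu, grd$th, k_mu, k_th)
  qa <- qr(A)
  models <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    le <- fld$lam_endo(f); lp <- fld$lam_epi(f)
    pe <- qr.coef(qa, le(grd$mu, grd$th))
    pp <- qr.coef(qa, lp(grd$mu, grd$th))
    models[[f]] <- lv_surface_model(
      c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
      coef_to_grid(pe, k_mu, k_th), coef_to_grid(pp, k_mu, k_th),
      basis_order = c(k_mu, k_th),
      focal_length = spec$endo_semi_axes_ed[3L])
  }
  base_plane <- slice_plane(c(0, 0, fld$base_height), c(0, 0, -1),
                            c(1, 0, 0), c(0, -1, 0))
  vols <- vapply(models, enclosed_volume, 0, surface = "endo",
                 base = base_plane, quadrature_order = quadrature_order)
  es_frame <- which.min(vols)
  myo_at <- function(f)
    enclosed_volume(models[[f]], "epi", base_plane, quadrature_order) - vols[f]
  true_mass <- 1.05 * mean(c(myo_at(1L), myo_at(es_frame)))

  # akinetic fraction from the analytic field geometry
  le_ed <- fld$lam_endo(1L); le_es <- fld$lam_endo(es_frame)
  lp_ed <- fld$lam_epi(1L)
  lam_mid <- function(mu, th) (le_ed(mu, th) + lp_ed(mu, th)) / 2
  excursion <- function(mu, th) abs(le_es(mu, th) - le_ed(mu, th))
  true_if <- midwall_area_fraction(
    lam_mid, numeric_dmu(lam_mid), numeric_dth(lam_mid), fld$base_height,
    function(mu, th) excursion(mu, th) < 0.1)

  structure(
    list(spec = spec, models = models, base_plane = base_plane,
         frame_volumes_ul = vols,
         true_edv = vols[1L], true_esv = vols[es_frame],
         true_sv = vols[1L] - vols[es_frame],
         true_ef = (vols[1L] - vols[es_frame]) / vols[1L],
         true_mass = true_mass, true_infarct_fraction = true_if,
         es_frame = es_frame, fields = fld),
    class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat("LV phantom truth:", x$spec$n_frames, "frames\n")
  cat(sprintf("  EDV %.1f ul  ESV %.1f ul  SV %.1f ul  EF %.1f%%\n",
              x$true_edv, x$true_esv, x$true_sv, 100 * x$true_ef))
  cat(sprintf("  mass %.1f mg  akinetic %.1f%%  (ES frame %d)\n",
              x$true_mass, x$true_infarct_fraction, x$es_frame))
  invisible(x)
}
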