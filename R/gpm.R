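# Guide-point modelling: fit the per-frame LV surface model to 3D data
# points derived from the study contours by penalized linear least squares
# in the radial field, and compute model-based volumes and mass.
#
# Every data point is assigned the parameter location whose radial ray (from
# the model centre) passes through it; for a star-shaped radial field this
# projection is exact, so the alternating project/solve scheme converges
# after a single refit.  The outer loop and its parameter-change stopping
# rule are retained for generality and for the fit diagnostics.

#' Fit configuration for guide-point modelling
#'
#' @param alpha1,alpha2 smoothing weights on the integrated squared first and
#'   second parametric derivatives of the radial field (mm^2 per unit
#'   parameter area).  They enforce the smooth, coherent geometry that lets
#'   the model interpolate between sparse slices; `alpha2` dominates the
#'   behaviour in unsampled regions.
#' @param alpha0 weight of a weak zeroth-order penalty pulling the radial
#'   field toward the reference model.  It is negligible against the data
#'   term wherever contours exist and anchors the basal region above the
#'   mitral-valve plane, where no image data constrain the surface.
#' @param max_outer_iterations cap on project/solve cycles.
#' @param projection_tolerance_mm stop when the largest change of any data
#'   point's assigned surface location falls below this.
#' @param quadrature_order quadrature order for model volumes.
#' @param basis_order `(n_mu, n_theta)` of the fitted coefficient grids.
#' @param rng_seed seed recorded for provenance (the fit is deterministic).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(alpha1 = 1e-3, alpha2 = 0.01, alpha0 = 0.1,
                       max_outer_iterations = 10L,
                       projection_tolerance_mm = 1e-6,
                       quadrature_order = 8L, basis_order = c(8L, 8L),
                       rng_seed = 1L) {
  stopifnot(alpha1 > 0, alpha2 > 0, alpha0 >= 0, projection_tolerance_mm > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha0 = alpha0,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 projection_tolerance_mm = projection_tolerance_mm,
                 quadrature_order = as.integer(quadrature_order),
                 basis_order = as.integer(basis_order),
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

#' Convert study contours to 3D guide points
#'
#' Maps every contour point of the included slices to the lab frame through
#' its slice plane.  Long-axis contour points basal to that frame's
#' mitral-valve plane (fitted to the four valve landmarks) are discarded, so
#' only ventricular points constrain the fit.
#'
#' @param study a [cine_study()].
#' @param included_slices indices into `study$slices`; `NULL` for all.
#' @return a data.frame with columns `x`, `y`, `z`, `surface`, `frame`,
#'   `weight`, `slice`, of class `guide_point_set`.
#' @export
contours_to_guidepoints <- function(study, included_slices = NULL) {
  if (is.null(included_slices)) included_slices <- seq_along(study$slices)
  if (!length(included_slices)) stop("contours_to_guidepoints: no slices")
  if (any(included_slices < 1L | included_slices > length(study$slices)))
    stop("contours_to_guidepoints: slice id not in study")
  mv <- lapply(seq_len(study$n_frames), function(f)
    fit_plane(study$mv_points[[f]], apex_hint = apex_estimate(study), frame = f))
  out <- list(); k <- 1L
  for (i in included_slices) {
    s <- study$slices[[i]]
    is_lax <- s$plane$slice_label != "SAX"
    for (f in seq_len(study$n_frames)) {
      for (surf in c("endo", "epi")) {
        uv <- s[[surf]][[f]]
        if (!nrow(uv)) next
        xyz <- plane_to_world(s$plane, uv)
        if (is_lax) {
          keep <- plane_distance(mv[[f]]$plane, xyz) >= 0
          xyz <- xyz[keep, , drop = FALSE]
          if (!nrow(xyz)) next
        }
        out[[k]] <- data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                               surface = surf, frame = f, weight = 1,
                               slice = i)
        k <- k + 1L
      }
    }
  }
  gps <- do.call(rbind, out)
  class(gps) <- c("guide_point_set", class(gps))
  gps
}

# apex estimate: centroid of the most apical SAX endocardial ED contour,
# extended half a slice thickness along the long axis
apex_estimate <- function(study) {
  lv <- lv_sax_indices(study)
  s <- study$slices[[lv[length(lv)]]]
  ctr <- plane_to_world(s$plane, colMeans(s$endo[[1L]]))
  mvc <- colMeans(study$mv_points[[1L]])
  axis_dir <- drop(ctr) - mvc
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  drop(ctr) + axis_dir * study$slice_thickness_mm / 2
}

#' Deterministic initial model from a study
#'
#' Builds an ellipsoidal initial surface pair: the long axis runs from the
#' mitral-valve landmark centroid to the apex estimate (most apical SAX
#' endocardial contour centroid extended half a slice), the endocardial
#' short radius is the mean distance of SAX endocardial points from the
#' axis, and the epicardial surface is offset outward by the mean SAX
#' epi-endo radius difference.
#'
#' @param study a [cine_study()].
#' @param cfg a [fit_config()].
#' @return an [lv_surface_model()] in the fit basis.
#' @export
initial_model <- function(study, cfg = fit_config()) {
  mvc <- colMeans(study$mv_points[[1L]])
  apex <- apex_estimate(study)
  u_hat <- (mvc - apex); L <- sqrt(sum(u_hat^2)); u_hat <- u_hat / L
  # the basal plane sits at roughly half the long semi-axis above the centre,
  # so apex-to-base covers ~1.5 semi-axes
  c_long <- L / 1.5
  centre <- apex + u_hat * c_long
  axis_dir <- -u_hat   # base -> apex
  radii <- function(surf) {
    rs <- unlist(lapply(lv_sax_indices(study), function(i) {
      s <- study$slices[[i]]
      xyz <- plane_to_world(s$plane, s[[surf]][[1L]])
      d <- sweep(xyz, 2L, centre)
      ax <- d %*% axis_dir
      sqrt(rowSums((d - ax %*% t(axis_dir))^2)
      )
    }))
    mean(rs)
  }
  a_endo <- radii("endo")
  a_epi <- max(radii("epi"), a_endo + 0.2)
  wall <- a_epi - a_endo
  # in-plane frame derived from the first valve landmark so the whole model
  # frame is equivariant under rigid transforms of the study
  u0 <- study$mv_points[[1L]][1L, ] - centre
  u0 <- u0 - sum(u0 * axis_dir) * axis_dir
  u0 <- u0 / sqrt(sum(u0^2))
  model_from_lambda(ellipsoid_lambda(a_endo, a_endo, c_long),
                    ellipsoid_lambda(a_epi, a_epi, c_long + wall),
                    axis_origin = centre, axis_direction = axis_dir,
                    axis_u = u0, axis_v = vcross(axis_dir, u0),
                    basis_order = cfg$basis_order, focal_length = c_long)
}

# quadratic-form smoothing penalties on the reduced coefficients
penalty_matrices <- function(k_mu, k_th) {
  gl <- pracma::gaussLegendre(24L, 0, 1)
  th <- seq(0, 2 * pi, length.out = 49L)[-49L]
  w_th <- 2 * pi / 48L
  g <- expand.grid(mu = gl$x, th = th)
  w <- rep(gl$w, length(th)) * w_th
  quad <- function(dmu, dth) {
    D <- reduced_design(g$mu, g$th, k_mu, k_th, dmu = dmu, dth = dth)
    crossprod(D * sqrt(w))
  }
  list(S0 = quad(0L, 0L),
       S1 = quad(1L, 0L) + quad(0L, 1L),
       S2 = quad(2L, 0L) + 2 * quad(1L, 1L) + quad(0L, 2L))
}

#' Fit per-frame surface models to guide points
#'
#' For each frame and surface, assigns each guide point its radial parameter
#' location on the current surface and solves the penalized least-squares
#' problem
#' \deqn{\min_\lambda \sum_i w_i (\lambda(\mu_i, \theta_i) - r_i)^2
#'   + \alpha_0 S_0[\lambda - \lambda_{ref}]
#'   + \alpha_1 S_1[\lambda - \lambda_{ref}]
#'   + \alpha_2 S_2[\lambda - \lambda_{ref}]}
#' where \eqn{r_i} is the point's radial distance from the model centre and
#' \eqn{S_1, S_2} are quadrature approximations of the integrated squared
#' first and second parametric derivatives.  Penalizing the deviation from
#' the reference field \eqn{\lambda_{ref}} (the previous frame's fit, or the
#' initial model for the first frame) rather than the field itself makes
#' unsampled regions follow the reference shape instead of flattening, which
#' is what lets the model interpolate across omitted slices.  The objective
#' is non-increasing across outer iterations; iteration stops when assigned
#' surface locations move less than the projection tolerance.  An
#' epicardial field that dips inside the endocardial one is repaired by a
#' uniform outward shift (logged as a message).
#'
#' @param gps a [contours_to_guidepoints()] result.
#' @param init an [initial_model()] (supplies centre, axis and basis).
#' @param cfg a [fit_config()].
#' @return list with `models` (per-frame [lv_surface_model()]s) and
#'   `diagnostics` (per-frame, per-surface objective traces, iteration
#'   counts and residual RMS in mm).
#' @export
fit_surfaces <- function(gps, init, cfg = fit_config()) {
  k_mu <- init$basis_order[1L]; k_th <- init$basis_order[2L]
  pen <- penalty_matrices(k_mu, k_th)
  P <- cfg$alpha1 * pen$S1 + cfg$alpha2 * pen$S2 + cfg$alpha0 * pen$S0
  p_ref <- list(endo = grid_to_coef(init$coeffs_endo),
                epi = grid_to_coef(init$coeffs_epi))
  frames <- sort(unique(gps$frame))
  models <- vector("list", max(frames))
  diag_list <- vector("list", max(frames))
  cur <- init
  for (f in frames) {
    gf <- gps[gps$frame == f, , drop = FALSE]
    coeffs <- list()
    objs <- list(endo = numeric(0), epi = numeric(0))
    rms <- c(endo = NA_real_, epi = NA_real_)
    n_iter <- 0L
    for (surf in c("endo", "epi")) {
      pts <- gf[gf$surface == surf, c("x", "y", "z"), drop = FALSE]
      if (nrow(pts) < 1L)
        stop("fit_surfaces: no ", surf, " guide points for frame ", f)
      wts <- gf$weight[gf$surface == surf]
      prm <- point_to_param(cur, as.matrix(pts))
      prev_loc <- NULL
      for (it in seq_len(cfg$max_outer_iterations)) {
        A <- reduced_design(prm[, "mu"], prm[, "theta"], k_mu, k_th)
        M <- crossprod(A * sqrt(wts)) + P
        rhs <- crossprod(A, wts * prm[, "r"]) + P %*% p_ref[[surf]]
        p_hat <- tryCatch(solve(M, rhs), error = function(e)
          stop("fit_surfaces: under-determined fit for frame ", f,
               " (", surf, "): ", conditionMessage(e)))
        resid <- drop(A %*% p_hat) - prm[, "r"]
        dp <- p_hat - p_ref[[surf]]
        objs[[surf]] <- c(objs[[surf]],
                          sum(wts * resid^2) + drop(t(dp) %*% P %*% dp))
        n_iter <- it
        loc <- cbind(prm[, "mu"], prm[, "theta"])
        if (!is.null(prev_loc) &&
            max(abs(loc - prev_loc)) * pi * mean(prm[, "r"]) <
              cfg$projection_tolerance_mm) break
        prev_loc <- loc
        # radial assignment is independent of the coefficients, so the
        # locations are already converged; re-derive them for the record
        prm <- point_to_param(cur, as.matrix(pts))
      }
      rms[surf] <- sqrt(mean(resid^2))
      coeffs[[surf]] <- coef_to_grid(p_hat, k_mu, k_th)
    }
    m <- lv_surface_model(cur$axis_origin, cur$axis_direction, cur$axis_u,
                          cur$axis_v, coeffs$endo, coeffs$epi,
                          basis_order = c(k_mu, k_th),
                          focal_length = init$focal_length)
    m <- repair_crossing(m, f)
    models[[f]] <- m
    diag_list[[f]] <- list(objective = objs, iterations = n_iter, rms_mm = rms)
    cur <- m
    p_ref <- list(endo = grid_to_coef(m$coeffs_endo),
                  epi = grid_to_coef(m$coeffs_epi))
  }
  list(models = models[frames], frames = frames, diagnostics = diag_list[frames])
}

# shift the epicardial field outward if it crosses inside the endocardial one
repair_crossing <- function(model, frame) {
  mu <- seq(0, 1, length.out = 64L)
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  g <- expand.grid(mu = mu, th = th)
  gap <- surface_lambda(model, "epi", g$mu, g$th) -
    surface_lambda(model, "endo", g$mu, g$th)
  if (min(gap) < 0) {
    shift <- -min(gap) + 0.01
    message("fit_surfaces: epicardial surface crossed endocardial at frame ",
            frame, "; shifted outward by ", signif(shift, 3), " mm")
    model$coeffs_epi <- model$coeffs_epi + shift
  }
  if (min(surface_lambda(model, "endo", g$mu, g$th)) <= 0)
    stop("fit_surfaces: fitted endocardial radius not positive at frame ",
         frame)
  model
}

#' Model-based global function
#'
#' Per-frame cavity volume by [enclosed_volume()] up to that frame's
#' mitral-valve plane; EDV and ESV are the maximal and minimal volumes over
#' the cycle (global-frame selection: the fitted model is 3D-coherent).  LV
#' mass is 1.05 times the mean over all frames of the epicardial minus
#' endocardial enclosed volume.  Papillary muscles are by convention part of
#' the cavity (the phantoms contain none).
#'
#' @param models per-frame models from [fit_surfaces()] (a list, or the
#'   `models` element of its result), or phantom truth models.
#' @param study the [cine_study()] supplying the mitral-valve landmarks.
#' @param cfg a [fit_config()].
#' @param method_label report label.
#' @return a [function_report()].
#' @export
gpm_function <- function(models, study, cfg = fit_config(),
                         method_label = "gpm") {
  if (!is.null(models$models)) models <- models$models
  nf <- study$n_frames
  stopifnot(length(models) == nf)
  cav <- myo <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- models[[f]]
    mv <- fit_plane(study$mv_points[[f]],
                    apex_hint = drop(surface_point(m, "endo", 1, 0)),
                    frame = f)
    cav[f] <- tryCatch(
      enclosed_volume(m, "endo", mv, cfg$quadrature_order),
      error = function(e) stop("gpm_function: frame ", f, ": ",
                               conditionMessage(e)))
    myo[f] <- enclosed_volume(m, "epi", mv, cfg$quadrature_order) - cav[f]
  }
  derive_function_report(max(cav), min(cav), mean(myo),
                         method_label = method_label)
}

#' One-call GPM analysis of a study under a protocol
#'
#' Applies the requested slice-reduction protocol, converts contours to
#' guide points, builds the deterministic initial model, fits all frames and
#' returns the model-based function report.
#'
#' @param study a full [cine_study()].
#' @param protocol `"full"`, `"six"` or `"four"`, or an integer vector of
#'   slice indices to include.
#' @param cfg a [fit_config()].
#' @return list with `report`, `models`, `diagnostics` and the reduced
#'   `study`.
#' @export
analyze_gpm <- function(study, protocol = "full", cfg = fit_config()) {
  if (is.character(protocol)) {
    protocol <- match.arg(protocol, c("full", "six", "four"))
    study_r <- switch(protocol, full = study, six = reduce_six(study),
                      four = reduce_four(study))
    label <- paste0("gpm_", protocol)
    included <- NULL
  } else {
    study_r <- study
    included <- protocol
    label <- "gpm_custom"
  }
  gps <- contours_to_guidepoints(study_r, included)
  init <- initial_model(study_r, cfg)
  fit <- fit_surfaces(gps, init, cfg)
  report <- gpm_function(fit$models, study_r, cfg, method_label = label)
  list(report = report, models = fit$models, diagnostics = fit$diagnostics,
       study = study_r)
}
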