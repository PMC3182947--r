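# Simulated cine acquisition: short-axis planes perpendicular to the LV long
# axis from just below the basal plane to the apex at fixed spacing, two
# long-axis planes through the axis, per-frame surface/plane intersection
# contours with isotropic in-plane Gaussian noise, and four mitral-valve
# landmarks where the basal intersection curve meets the long-axis planes.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Construct / validate a cine study
#'
#' A `cine_study` is one animal's dataset: a list of slices (each a
#' [slice_plane()] with per-frame endocardial and epicardial contours in
#' plane coordinates), the four mitral-valve landmark points per frame, and
#' acquisition metadata.
#'
#' @param slices list of `list(plane, endo, epi)`; `endo` and `epi` are lists
#'   (one per frame) of n x 2 `(u, v)` matrices in mm.
#' @param mv_points list (one per frame) of 4 x 3 lab-frame matrices.
#' @param n_frames number of frames.
#' @param slice_thickness_mm,pixel_size_mm acquisition geometry.
#' @param meta free-form metadata list.
#' @return an object of class `cine_study`.
#' @export
cine_study <- function(slices, mv_points, n_frames, slice_thickness_mm,
                       pixel_size_mm, meta = list()) {
  study <- structure(
    list(slices = slices, mv_points = mv_points, n_frames = as.integer(n_frames),
         slice_thickness_mm = slice_thickness_mm, pixel_size_mm = pixel_size_mm,
         meta = meta),
    class = "cine_study")
  validate_cine_study(study)
}

validate_cine_study <- function(study) {
  labs <- vapply(study$slices, function(s) s$plane$slice_label, "")
  if (sum(labs == "LAX_2CH") != 1L || sum(labs == "LAX_4CH") != 1L)
    stop("cine_study: exactly one LAX_2CH and one LAX_4CH slice required")
  sax <- study$slices[labs == "SAX"]
  if (length(sax) >= 2L) {
    n1 <- sax[[1L]]$plane$normal
    for (s in sax[-1L])
      if (max(abs(abs(sum(s$plane$normal * n1)) - 1)) > 1e-9)
        stop("cine_study: SAX planes are not parallel")
    off <- vapply(sax, function(s) sum(s$plane$origin * n1), 0)
    sp <- diff(sort(off))
    # reduced protocols omit slices, so spacings are integer multiples of
    # the slice thickness; contiguity itself is checked by slice_summation
    mult <- sp / study$slice_thickness_mm
    if (length(sp) && max(abs(mult - round(mult))) > 1e-6)
      stop("cine_study: SAX planes are not on the slice_thickness_mm grid")
  }
  if (length(study$mv_points) != study$n_frames)
    stop("cine_study: mv_points must be present for every frame")
  for (s in study$slices)
    if (length(s$endo) != study$n_frames || length(s$epi) != study$n_frames)
      stop("cine_study: contour lists must have one entry per frame")
  study
}

sax_slices <- function(study) {
  keep <- vapply(study$slices, function(s) s$plane$slice_label == "SAX", TRUE)
  study$slices[keep]
}

#' Simulate slice acquisition from a phantom
#'
#' Places SAX planes perpendicular to the phantom long axis from the basal
#' plane toward the apex at `slice_thickness_mm` spacing (slice centres at
#' half-spacing offsets, kept while the epicardial surface is still cut),
#' adds the two orthogonal LAX planes through the axis, intersects every
#' surface with every plane in every frame, and perturbs contour points and
#' mitral-valve landmarks with i.i.d. isotropic in-plane Gaussian noise.
#' Fully reproducible from `rng_seed`.
#'
#' @param truth a [make_phantom()] result.
#' @param slice_thickness_mm SAX spacing and thickness (mm).
#' @param pixel_size_mm in-plane pixel size recorded for rasterized analysis.
#' @param n_contour_points points per SAX contour (LAX contours use twice as
#'   many).
#' @param noise_sd_mm in-plane noise SD (mm); `NULL` uses the phantom spec.
#' @param rng_seed integer; `NULL` uses the phantom spec.
#' @param lax_angle_rad azimuth of the two-chamber LAX plane's in-plane
#'   direction; the four-chamber plane is orthogonal.
#' @return a [cine_study()].
#' @export
acquire_study <- function(truth, slice_thickness_mm = 1, pixel_size_mm = 0.05,
                          n_contour_points = 64L, noise_sd_mm = NULL,
                          rng_seed = NULL, lax_angle_rad = 0) {
  stopifnot(inherits(truth, "truth_model"))
  if (is.null(noise_sd_mm)) noise_sd_mm <- truth$spec$noise_sd_mm
  if (is.null(rng_seed)) rng_seed <- truth$spec$rng_seed
  n_frames <- truth$spec$n_frames
  m1 <- truth$models[[1L]]
  ctr <- m1$axis_origin; d <- m1$axis_direction
  h <- sum((truth$base_plane$origin - ctr) * (-d))   # basal height above centre
  # apical epicardial extent (most apical over the cycle is end-diastole)
  apex_extent <- max(vapply(truth$models, function(m)
    surface_lambda(m, "epi", 1, 0), 0))
  z <- h - slice_thickness_mm / 2
  sax_planes <- list(); k <- 1L
  while (z > -apex_extent) {
    origin <- ctr + (-d) * z
    sax_planes[[k]] <- slice_plane(origin, d, m1$axis_u, m1$axis_v,
                                   slice_label = "SAX", sax_index = k)
    z <- z - slice_thickness_mm; k <- k + 1L
  }
  if (length(sax_planes) < 2L)
    stop("acquire_study: stack would contain fewer than 2 SAX slices")
  u2 <- cos(lax_angle_rad) * m1$axis_u + sin(lax_angle_rad) * m1$axis_v
  u4 <- -sin(lax_angle_rad) * m1$axis_u + cos(lax_angle_rad) * m1$axis_v
  lax_planes <- list(
    slice_plane(ctr, vcross(u2, d), axis_u = u2, axis_v = -d,
                slice_label = "LAX_2CH"),
    slice_plane(ctr, vcross(u4, d), axis_u = u4, axis_v = -d,
                slice_label = "LAX_4CH"))

  with_seed(rng_seed, {
    # contour points are spaced ~0.15 mm along the contour (as an observer
    # would place them), with a floor of 12 points; small apical contours
    # therefore carry fewer points and noisy points cannot overtake their
    # neighbours along the curve
    contour_of <- function(model, surface, plane, n_pts) {
      res <- intersect_surface_with_plane(model, surface, plane,
                                          max(256L, n_pts))
      uv <- res$uv
      if (nrow(uv)) {
        seg <- sqrt(rowSums((uv[c(2:nrow(uv), 1L), ] - uv)^2))
        per <- sum(seg)
        # structures below ~1 mm circumference (a few pixels across) are not
        # reliably segmentable and are treated as absent
        if (per < 1) return(uv[0L, , drop = FALSE])
        # keep points at ~uniform arclength so noise cannot reorder
        # neighbouring points along the curve
        n_keep <- max(8L, min(n_pts, round(per / 0.15)))
        s_cum <- c(0, cumsum(seg[-length(seg)]))
        targets <- (seq_len(n_keep) - 1L) * per / n_keep
        idx <- unique(vapply(targets, function(t)
          which.min(abs(s_cum - t)), 0L))
        uv <- uv[idx, , drop = FALSE]
        if (noise_sd_mm > 0)
          uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_sd_mm), ncol = 2L)
      }
      uv
    }
    slices <- lapply(c(sax_planes, lax_planes), function(pl) {
      n_pts <- if (pl$slice_label == "SAX") n_contour_points
               else 2L * n_contour_points
      endo <- lapply(truth$models, contour_of, surface = "endo", plane = pl,
                     n_pts = n_pts)
      epi <- lapply(truth$models, contour_of, surface = "epi", plane = pl,
                    n_pts = n_pts)
      list(plane = pl, endo = endo, epi = epi)
    })
    # mitral-valve landmarks: basal intersection curve meets the LAX planes
    mv_points <- lapply(seq_len(n_frames), function(f) {
      m <- truth$models[[f]]
      pts <- lapply(c(0, pi / 2), function(off) {
        vapply(c(lax_angle_rad + off, lax_angle_rad + off + pi), function(t) {
          fz <- function(mu)
            plane_distance(truth$base_plane, surface_point(m, "endo", mu, t))
          mu_star <- stats::uniroot(fz, c(1e-6, 1), tol = 1e-13)$root
          drop(surface_point(m, "endo", mu_star, t))
        }, numeric(3L))
      })
      p4 <- t(cbind(pts[[1L]], pts[[2L]]))
      if (noise_sd_mm > 0) {
        for (i in 1:2) {
          pl <- lax_planes[[i]]
          nse <- matrix(stats::rnorm(4L, 0, noise_sd_mm), 2L, 2L)
          idx <- (2L * i - 1L):(2L * i)
          p4[idx, ] <- p4[idx, ] +
            nse %*% rbind(pl$axis_u, pl$axis_v)
        }
      }
      p4
    })
    cine_study(slices, mv_points, n_frames, slice_thickness_mm, pixel_size_mm,
               meta = list(rng_seed = rng_seed, noise_sd_mm = noise_sd_mm,
                           protocol = "full",
                           group = if (is.null(truth$spec$infarct)) "control"
                                   else "infarct"))
  })
}
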