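# Standard analysis: a surrogate for manual voxel-count volumetry.  Per-slice
# contour areas are obtained by counting pixel centres inside the contour
# polygon, end-diastolic and end-systolic frames are selected per slice as
# the frames of maximal and minimal cavity area, and volumes follow by slice
# summation over the contiguous SAX stack.

# TRUE if the closed polygon has no crossing edges (adjacent edges share a
# vertex and are ignored)
polygon_is_simple <- function(uv) {
  n <- nrow(uv)
  if (n < 4L) return(TRUE)
  p1 <- uv; p2 <- uv[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    j <- setdiff((i + 2L):n, if (i == 1L) n else integer(0))
    if (!length(j)) next
    d1x <- p2[i, 1L] - p1[i, 1L]; d1y <- p2[i, 2L] - p1[i, 2L]
    d2x <- p2[j, 1L] - p1[j, 1L]; d2y <- p2[j, 2L] - p1[j, 2L]
    den <- cross2(d1x, d1y, d2x, d2y)
    ex <- p1[j, 1L] - p1[i, 1L]; ey <- p1[j, 2L] - p1[i, 2L]
    t1 <- cross2(ex, ey, d2x, d2y) / den
    t2 <- cross2(ex, ey, d1x, d1y) / den
    hit <- is.finite(t1) & is.finite(t2) &
      t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# count of pixel centres (on a lab-aligned grid of pitch px) inside polygon
pixel_count <- function(uv, px) {
  if (nrow(uv) < 3L) return(0L)
  xs <- seq(floor(min(uv[, 1L]) / px) * px + px / 2, max(uv[, 1L]), by = px)
  ys <- seq(floor(min(uv[, 2L]) / px) * px + px / 2, max(uv[, 2L]), by = px)
  if (!length(xs) || !length(ys)) return(0L)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  bnd <- rbind(uv, uv[1L, ])
  sum(mgcv::in.out(bnd, g))
}

#' Rasterized cavity and myocardial areas of one slice/frame
#'
#' Areas are pixel counts times the pixel area, emulating voxel-count
#' segmentation: the cavity area counts pixel centres inside the endocardial
#' contour, the myocardial area is the epicardial count minus the
#' endocardial count.
#'
#' @param study a [cine_study()].
#' @param slice slice index into `study$slices`.
#' @param frame frame index.
#' @param pixel_size_mm pixel pitch; defaults to the study's.
#' @return list with `cavity_area` and `myocardial_area` (mm^2).
#' @export
rasterized_slice_areas <- function(study, slice, frame,
                                   pixel_size_mm = study$pixel_size_mm) {
  s <- study$slices[[slice]]
  endo <- s$endo[[frame]]; epi <- s$epi[[frame]]
  for (nm in c("endo", "epi")) {
    uv <- if (nm == "endo") endo else epi
    if (nrow(uv) >= 3L && !polygon_is_simple(uv))
      stop("rasterized_slice_areas: self-intersecting ", nm,
           " contour at slice ", slice, ", frame ", frame)
  }
  n_endo <- pixel_count(endo, pixel_size_mm)
  n_epi <- pixel_count(epi, pixel_size_mm)
  list(cavity_area = n_endo * pixel_size_mm^2,
       myocardial_area = (n_epi - n_endo) * pixel_size_mm^2)
}

#' Per-slice end-diastolic and end-systolic frame selection
#'
#' The ED frame is the frame of maximal cavity area for the slice, the ES
#' frame the frame of minimal cavity area; ties break toward the earliest
#' frame.  A slice with no cavity in any frame cannot be classified and
#' returns `NULL` with a warning.
#'
#' @param cavity_areas numeric vector of per-frame cavity areas (mm^2).
#' @return list with `ed_frame` and `es_frame` (1-based), or `NULL`.
#' @export
select_ed_es_per_slice <- function(cavity_areas) {
  if (length(cavity_areas) < 2L)
    stop("select_ed_es_per_slice: need at least 2 frames")
  if (all(cavity_areas == 0)) {
    warning("select_ed_es_per_slice: slice has no cavity in any frame; excluded")
    return(NULL)
  }
  list(ed_frame = which.max(cavity_areas), es_frame = which.min(cavity_areas))
}

#' Standard slice-summation volumetry
#'
#' Computes EDV and ESV by summing per-slice rasterized cavity areas times
#' the slice thickness over the contiguous SAX stack, with per-slice ED/ES
#' frame selection (the per-slice rule of manual analysis; a global-frame
#' mode is available for sensitivity analysis).  LV mass is 1.05 times the
#' mean of the end-diastolic and end-systolic myocardial volumes.  Apical
#' slices containing myocardium but no cavity use the stack-median ED/ES
#' frames.  A slice counts fully if its contour is non-empty; no partial
#' volume correction is applied.
#'
#' @param study a [cine_study()] with a contiguous SAX stack.
#' @param pixel_size_mm rasterization pitch.
#' @param per_slice logical; `FALSE` selects global ED/ES frames from the
#'   summed cavity volume instead of per slice.
#' @return a [function_report()] labelled `"standard"`.
#' @export
slice_summation <- function(study, pixel_size_mm = study$pixel_size_mm,
                            per_slice = TRUE) {
  sax <- sax_slices(study)
  sax <- sax[order(vapply(sax, function(s) s$plane$sax_index, 0L))]
  if (length(sax) < 2L) stop("slice_summation: need at least 2 SAX slices")
  n1 <- sax[[1L]]$plane$normal
  off <- vapply(sax, function(s) sum(s$plane$origin * n1), 0)
  sp <- abs(diff(off))
  if (max(abs(sp - study$slice_thickness_mm)) > 1e-6)
    stop("slice_summation: SAX stack is not contiguous at the stated ",
         "slice thickness; the standard method requires contiguous slices")
  th <- study$slice_thickness_mm
  nf <- study$n_frames
  idx <- match(vapply(sax, function(s) s$plane$sax_index, 0L),
               vapply(study$slices, function(s) s$plane$sax_index, 0L))
  cav <- matrix(0, length(sax), nf)
  for (i in seq_along(sax))
    for (f in seq_len(nf))
      cav[i, f] <- rasterized_slice_areas(study, idx[i], f,
                                          pixel_size_mm)$cavity_area
  sel <- apply(cav, 1L, function(a)
    withCallingHandlers(select_ed_es_per_slice(a),
                        warning = function(w) invokeRestart("muffleWarning")))
  if (!per_slice) {
    tot <- colSums(cav)
    gf <- list(ed_frame = which.max(tot), es_frame = which.min(tot))
    sel <- rep(list(gf), length(sax))
  }
  has_cav <- !vapply(sel, is.null, TRUE)
  if (!any(has_cav)) stop("slice_summation: no slice contains a cavity")
  med_ed <- round(stats::median(vapply(sel[has_cav], `[[`, 0L, "ed_frame")))
  med_es <- round(stats::median(vapply(sel[has_cav], `[[`, 0L, "es_frame")))
  edv <- esv <- myo_ed <- myo_es <- 0
  for (i in seq_along(sax)) {
    ed <- if (has_cav[i]) sel[[i]]$ed_frame else med_ed
    es <- if (has_cav[i]) sel[[i]]$es_frame else med_es
    edv <- edv + cav[i, ed] * th
    esv <- esv + cav[i, es] * th
    myo_ed <- myo_ed + rasterized_slice_areas(study, idx[i], ed,
                                              pixel_size_mm)$myocardial_area * th
    myo_es <- myo_es + rasterized_slice_areas(study, idx[i], es,
                                              pixel_size_mm)$myocardial_area * th
  }
  derive_function_report(edv, esv, mean(c(myo_ed, myo_es)),
                         method_label = "standard")
}

#' Infarct size as the relative area of akinetic myocardium
#'
#' Measures, on the end-diastolic mid-wall surface between the basal plane
#' and the apex, the percentage of surface area whose endocardial
#' end-diastole to end-systole radial excursion is below the akinesia
#' threshold `tau`.
#'
#' @param models list of per-frame [lv_surface_model()]s (frame 1 =
#'   end-diastole), e.g. phantom truth models or fitted GPM models.
#' @param base_plane the basal truncation plane.
#' @param tau akinesia threshold on radial excursion (mm).
#' @param es_frame end-systolic frame; if `NULL`, the frame of minimal
#'   cavity volume.
#' @param n_grid sampling grid per parameter for the mid-wall quadrature.
#' @return infarct size in % of LV myocardial surface.
#' @export
infarct_size <- function(models, base_plane, tau = 0.1, es_frame = NULL,
                         n_grid = c(64L, 64L)) {
  if (length(models) < 2L)
    stop("infarct_size: end-systolic geometry missing (need >= 2 frames)")
  if (is.null(es_frame)) {
    vols <- vapply(models, enclosed_volume, 0, surface = "endo",
                   base = base_plane, quadrature_order = 6L)
    es_frame <- which.min(vols)
  }
  m_ed <- models[[1L]]; m_es <- models[[es_frame]]
  bh <- sum((base_plane$origin - m_ed$axis_origin) *
              (-m_ed$axis_direction))
  lam_mid <- function(mu, th)
    (surface_lambda(m_ed, "endo", mu, th) +
       surface_lambda(m_ed, "epi", mu, th)) / 2
  lam_dmu <- function(mu, th)
    (surface_lambda(m_ed, "endo", mu, th, dmu = 1L) +
       surface_lambda(m_ed, "epi", mu, th, dmu = 1L)) / 2
  lam_dth <- function(mu, th)
    (surface_lambda(m_ed, "endo", mu, th, dth = 1L) +
       surface_lambda(m_ed, "epi", mu, th, dth = 1L)) / 2
  midwall_area_fraction(
    lam_mid, lam_dmu, lam_dth, bh,
    function(mu, th) abs(surface_lambda(m_es, "endo", mu, th) -
                           surface_lambda(m_ed, "endo", mu, th)) < tau,
    n_mu = n_grid[1L], n_th = n_grid[2L])
}
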