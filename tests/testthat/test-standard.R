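# scanline even-odd fill: an independent rasterization oracle sharing no code
# with the package's point-in-polygon counting
scanline_count <- function(uv, px) {
  xs <- seq(floor(min(uv[, 1]) / px) * px + px / 2, max(uv[, 1]), by = px)
  ys <- seq(floor(min(uv[, 2]) / px) * px + px / 2, max(uv[, 2]), by = px)
  n <- nrow(uv)
  x1 <- uv[, 1]; y1 <- uv[, 2]
  x2 <- uv[c(2:n, 1), 1]; y2 <- uv[c(2:n, 1), 2]
  total <- 0L
  for (y in ys) {
    crossing <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crossing)) next
    xc <- x1[crossing] + (y - y1[crossing]) /
      (y2[crossing] - y1[crossing]) * (x2[crossing] - x1[crossing])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L))
      total <- total + sum(xs > xc[k] & xs < xc[k + 1L])
  }
  total
}

circle_uv <- function(r, n = 96L, ctr = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

two_slice_study <- function(endo1, epi1, endo2 = endo1, epi2 = epi1) {
  mk <- function(k, endo, epi)
    list(plane = slice_plane(c(0, 0, -(k - 1)), c(0, 0, -1), c(1, 0, 0),
                             c(0, -1, 0), slice_label = "SAX", sax_index = k),
         endo = list(endo, endo * 0.9), epi = list(epi, epi))
  lax <- lapply(c("LAX_2CH", "LAX_4CH"), function(lab) {
    u <- if (lab == "LAX_2CH") c(1, 0, 0) else c(0, 1, 0)
    list(plane = slice_plane(c(0, 0, 0), vcross_test(u, c(0, 0, -1)), u,
                             c(0, 0, 1), slice_label = lab),
         endo = rep(list(circle_uv(1.5)), 2L),
         epi = rep(list(circle_uv(2)), 2L))
  })
  mv <- rep(list(rbind(c(1.5, 0, .5), c(-1.5, 0, .5), c(0, 1.5, .5),
                       c(0, -1.5, .5))), 2L)
  cine_study(c(list(mk(1L, endo1, epi1), mk(2L, endo2, epi2)), lax),
             mv, 2L, 1, 0.05)
}

test_that("rasterized areas converge to exact polygon areas", {
  st <- two_slice_study(circle_uv(2), circle_uv(2.8))
  a <- rasterized_slice_areas(st, 1L, 1L, 0.05)
  expect_lt(abs(a$cavity_area / (pi * 4) - 1), 0.01)
  expect_lt(abs((a$cavity_area + a$myocardial_area) / (pi * 2.8^2) - 1), 0.01)
  # rasterization error decreases with pixel size; averaged over an ensemble
  # of star-shaped polygons against their exact shoelace areas, which
  # isolates the rasterization step from slice-direction discretization
  set.seed(4)
  polys <- lapply(1:12, function(i)
    circle_uv(1, n = 24L) * (1.2 + 0.5 * runif(24L)))
  mean_err <- function(px) {
    mean(vapply(polys, function(p) {
      sh <- abs(sum(p[, 1] * p[c(2:24, 1), 2] - p[c(2:24, 1), 1] * p[, 2]) / 2)
      sst <- two_slice_study(p, p * 2)
      abs(rasterized_slice_areas(sst, 1L, 1L, px)$cavity_area - sh)
    }, 0))
  }
  errs <- vapply(c(0.2, 0.1, 0.05), mean_err, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("identical endo and epi contours give zero myocardial area", {
  st <- two_slice_study(circle_uv(2), circle_uv(2))
  expect_equal(rasterized_slice_areas(st, 1L, 1L, 0.05)$myocardial_area, 0)
})

test_that("pixel counting matches an even-odd scanline oracle exactly", {
  set.seed(21)
  for (rep in 1:5) {
    r <- 1 + 0.6 * runif(24L)
    star <- circle_uv(1)
    star <- star * r   # star-shaped polygon
    st <- two_slice_study(star, star * 1.5)
    a <- rasterized_slice_areas(st, 1L, 1L, 0.1)
    expect_identical(a$cavity_area / 0.1^2, as.numeric(scanline_count(star, 0.1)))
  }
})

test_that("self-intersecting contours raise a topology error with location", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  st <- two_slice_study(bow, circle_uv(2))
  expect_error(rasterized_slice_areas(st, 1L, 1L, 0.05),
               "self-intersecting endo contour at slice 1, frame 1")
})

test_that("per-slice ED/ES selection follows extremal areas with early ties", {
  expect_equal(select_ed_es_per_slice(c(5, 3, 1, 3, 5)),
               list(ed_frame = 1L, es_frame = 3L))
  expect_equal(select_ed_es_per_slice(c(2, 2, 2)),
               list(ed_frame = 1L, es_frame = 1L))
  expect_warning(res <- select_ed_es_per_slice(c(0, 0, 0)), "no cavity")
  expect_null(res)
  expect_error(select_ed_es_per_slice(c(1)), "2 frames")
})

test_that("slice summation is exact for cylinders and additive over substacks", {
  st <- two_slice_study(circle_uv(2), circle_uv(2.8))
  r <- slice_summation(st, pixel_size_mm = 0.05)
  a1 <- rasterized_slice_areas(st, 1L, 1L, 0.05)$cavity_area
  expect_equal(r$edv_ul, 2 * a1)   # area x 1 mm per slice, both slices equal
  expect_equal(r$sv_ul, r$edv_ul - r$esv_ul)

  # additivity: the 8-slice control stack split into two 4-slice substacks
  full <- ctl_study0()
  labs <- vapply(full$slices, function(s) s$plane$slice_label, "")
  sax <- which(labs == "SAX"); lax <- which(labs != "SAX")
  sub <- function(keep) {
    s <- full; s$slices <- full$slices[c(keep, lax)]; s
  }
  tot <- slice_summation(full, pixel_size_mm = 0.1)
  p1 <- slice_summation(sub(sax[1:4]), pixel_size_mm = 0.1)
  p2 <- suppressWarnings(slice_summation(sub(sax[5:8]), pixel_size_mm = 0.1))
  expect_equal(p1$edv_ul + p2$edv_ul, tot$edv_ul, tolerance = 1e-12)
  expect_equal(p1$esv_ul + p2$esv_ul, tot$esv_ul, tolerance = 1e-12)
})

test_that("slice summation recovers phantom EDV and the truth ES frame", {
  ph <- ctl_phantom()
  st <- ctl_study0()
  r <- slice_summation(st)
  expect_lt(abs(r$edv_ul / ph$true_edv - 1), 0.04)
  expect_lt(abs(r$esv_ul / ph$true_esv - 1), 0.06)
  # mid-ventricular slices pick the truth ES frame
  for (i in lvgpm:::lv_sax_indices(st)[3:5]) {
    areas <- vapply(seq_len(st$n_frames), function(f)
      rasterized_slice_areas(st, i, f, 0.1)$cavity_area, 0)
    expect_equal(select_ed_es_per_slice(areas)$es_frame, ph$es_frame)
  }
})

test_that("standard analysis requires a contiguous stack", {
  full <- ctl_study0()
  labs <- vapply(full$slices, function(s) s$plane$slice_label, "")
  gap <- full
  gap$slices <- full$slices[c(which(labs == "SAX")[c(1, 3, 5)],
                              which(labs != "SAX"))]
  expect_error(slice_summation(gap), "contiguous")
})

test_that("thicker slices do not improve accuracy on average", {
  errs <- function(th) {
    vapply(1:6, function(s) {
      ph <- make_phantom(phantom_spec(n_frames = 4L, rng_seed = s))
      st <- acquire_study(ph, slice_thickness_mm = th)
      abs(slice_summation(st, pixel_size_mm = 0.1)$edv_ul - ph$true_edv)
    }, 0)
  }
  expect_gte(mean(errs(2)), mean(errs(1)))
})

test_that("infarct size is zero without akinesia and total without motion", {
  ph <- ctl_phantom()
  expect_equal(infarct_size(ph$models, ph$base_plane, es_frame = ph$es_frame),
               0)
  frozen <- make_phantom(phantom_spec(n_frames = 4L, contraction_fraction = 0,
                                      long_axis_contraction_fraction = 0))
  expect_equal(infarct_size(frozen$models, frozen$base_plane, es_frame = 3L),
               100)
  expect_error(infarct_size(ph$models[1L], ph$base_plane), "2 frames")
})
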