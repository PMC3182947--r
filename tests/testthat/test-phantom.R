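test_that("control phantom defaults reproduce mouse-scale physiology", {
  ph <- ctl_phantom()
  # end-diastolic volume: closed-form target near 64 ul
  a <- ph$spec$endo_semi_axes_ed
  h <- ph$spec$base_truncation_fraction * a[3]
  exact <- truncated_ellipsoid_volume(a[1], a[2], a[3], h)
  expect_lt(abs(ph$true_edv / exact - 1), 0.005)
  expect_lt(abs(ph$true_edv - 64) / 64, 0.05)
  # truth self-consistency is exact
  expect_identical(ph$true_ef, (ph$true_edv - ph$true_esv) / ph$true_edv)
  expect_identical(ph$true_sv, ph$true_edv - ph$true_esv)
  expect_lt(ph$true_esv, ph$true_edv)
  # frame 1 is end-diastole, mid-cycle is end-systole
  expect_equal(which.max(ph$frame_volumes_ul), 1L)
  expect_equal(ph$es_frame, ph$spec$n_frames / 2 + 1L)
})

test_that("the wall is volume-conserving across the cycle", {
  ph <- ctl_phantom()
  myo <- vapply(c(1L, 3L, ph$es_frame), function(f)
    enclosed_volume(ph$models[[f]], "epi", ph$base_plane, 8L) -
      enclosed_volume(ph$models[[f]], "endo", ph$base_plane, 8L), 0)
  expect_lt(max(abs(myo / myo[1] - 1)), 0.005)
})

test_that("zero contraction gives zero ejection fraction", {
  ph <- make_phantom(phantom_spec(n_frames = 4L, contraction_fraction = 0,
                                  long_axis_contraction_fraction = 0))
  expect_equal(ph$true_ef, 0, tolerance = 1e-9)
})

test_that("an akinetic infarct depresses EF without abolishing it", {
  ph0 <- ctl_phantom()
  spec <- phantom_spec(n_frames = 8L,
                       infarct = list(center_theta = 2.6, center_mu = 0.6,
                                      angular_halfwidth = pi / 2,
                                      mu_halfwidth = 0.3,
                                      wall_thinning_fraction = 0,
                                      bulge_mm = 0, akinetic = TRUE))
  ph <- make_phantom(spec)
  expect_gt(ph$true_ef, 0)
  expect_lt(ph$true_ef, ph0$true_ef)
})

test_that("phantom truth volumes agree with 20-um voxel counting", {
  ph <- ctl_phantom()
  fld <- ph$fields
  vv <- voxelized_volume(ph$models[[1L]], "endo", ph$base_plane,
                         voxel_mm = 0.02, lambda_fn = fld$lam_endo(1L))
  expect_lt(abs(vv / ph$true_edv - 1), 0.005)
})

test_that("spec validation lists every offending field", {
  expect_error(phantom_spec(endo_semi_axes_ed = c(-1, 2, 3),
                            contraction_fraction = 2),
               "endo_semi_axes_ed.*contraction_fraction")
  expect_error(phantom_spec(infarct = list(center_theta = 0)), "infarct\\$")
  expect_error(
    phantom_spec(infarct = list(center_theta = 0, center_mu = 0.9,
                                angular_halfwidth = 1, mu_halfwidth = 0.3,
                                wall_thinning_fraction = 0.2, bulge_mm = 0,
                                akinetic = TRUE)),
    "parameter domain")
})

test_that("acquisition geometry matches the imaging protocol", {
  st <- ctl_study0()
  labs <- vapply(st$slices, function(s) s$plane$slice_label, "")
  n_lv <- length(lvgpm:::lv_sax_indices(st))
  expect_gte(n_lv, 7L); expect_lte(n_lv, 9L)
  expect_equal(sum(labs == "LAX_2CH"), 1L)
  expect_equal(sum(labs == "LAX_4CH"), 1L)
  expect_length(st$mv_points, st$n_frames)
  # noise-free contour points lie on the truth surface
  ph <- ctl_phantom()
  for (i in c(2L, which(labs == "LAX_2CH"))) {
    s <- st$slices[[i]]
    xyz <- plane_to_world(s$plane, s$endo[[3L]])
    prm <- lvgpm:::point_to_param(ph$models[[3L]], xyz)
    lam <- surface_lambda(ph$models[[3L]], "endo", prm[, "mu"], prm[, "theta"])
    expect_lt(max(abs(prm[, "r"] - lam)), 1e-6)
  }
  # mitral-valve landmarks lie on the basal plane
  expect_lt(max(abs(plane_distance(ph$base_plane, st$mv_points[[5L]]))), 1e-9)
})

test_that("acquisition is reproducible from its seed", {
  ph <- make_phantom(phantom_spec(n_frames = 2L, rng_seed = 123L))
  s1 <- acquire_study(ph)
  s2 <- acquire_study(ph)
  expect_identical(s1, s2)
  s3 <- acquire_study(ph, rng_seed = 124L)
  expect_false(identical(s1$slices[[2L]]$endo[[1L]],
                         s3$slices[[2L]]$endo[[1L]]))
})

test_that("infarct fraction from the window geometry matches the surfaces", {
  ph <- inf_phantom()
  measured <- infarct_size(ph$models, ph$base_plane, es_frame = ph$es_frame)
  expect_lt(abs(measured - ph$true_infarct_fraction), 1)
})
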