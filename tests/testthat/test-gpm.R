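test_that("guide points are the 3D contour points below the valve plane", {
  st <- ctl_study0()
  gps <- contours_to_guidepoints(st)
  expect_true(all(c("x", "y", "z", "surface", "frame", "weight", "slice")
                  %in% names(gps)))
  # counting oracle: every stored contour point appears except LAX points
  # basal to the frame's fitted valve plane
  expected <- 0L
  for (i in seq_along(st$slices)) {
    s <- st$slices[[i]]
    for (f in seq_len(st$n_frames)) for (surf in c("endo", "epi")) {
      uv <- s[[surf]][[f]]
      if (!nrow(uv)) next
      if (s$plane$slice_label == "SAX") expected <- expected + nrow(uv)
      else {
        mv <- fit_plane(st$mv_points[[f]], apex_hint = c(0, 0, -10))
        xyz <- plane_to_world(s$plane, uv)
        expected <- expected + sum(plane_distance(mv$plane, xyz) >= 0)
      }
    }
  }
  expect_identical(nrow(gps), expected)
  expect_error(contours_to_guidepoints(st, 99L), "slice id")
})

test_that("fitting recovers a model lying in the basis span", {
  cfg <- fit_config(alpha0 = 1e-9, alpha1 = 1e-9, alpha2 = 1e-9)
  truth <- model_from_lambda(ellipsoid_lambda(2, 2, 4),
                             ellipsoid_lambda(3, 3, 5),
                             basis_order = cfg$basis_order)
  g <- expand.grid(mu = seq(0.02, 0.98, length.out = 40L),
                   th = seq(0, 2 * pi, length.out = 17L)[-17L])
  mk <- function(surf) {
    pts <- surface_point(truth, surf, g$mu, g$th)
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], surface = surf,
               frame = 1L, weight = 1, slice = 1L)
  }
  fit <- fit_surfaces(rbind(mk("endo"), mk("epi")), truth, cfg)
  m <- fit$models[[1L]]
  expect_lt(max(abs(m$coeffs_endo - truth$coeffs_endo)), 1e-4)
  expect_lt(max(abs(m$coeffs_epi - truth$coeffs_epi)), 1e-4)
  expect_lt(abs(enclosed_volume(m, "endo", NULL, 8) /
                  enclosed_volume(truth, "endo", NULL, 8) - 1), 1e-3)
  expect_lt(fit$diagnostics[[1L]]$rms_mm["endo"], 1e-8)
})

test_that("full-slice GPM recovers the control phantom within tight bounds", {
  ph <- ctl_phantom()
  res <- analyze_gpm(ctl_study0(), "full")
  expect_lt(abs(res$report$edv_ul / ph$true_edv - 1), 0.03)
  expect_lt(abs(res$report$esv_ul / ph$true_esv - 1), 0.03)
  expect_lt(abs(res$report$lvm_mg / ph$true_mass - 1), 0.03)
  expect_lt(abs(res$report$ef_fraction - ph$true_ef), 0.04)
})

test_that("truth models passed straight through reproduce the truth report", {
  ph <- ctl_phantom()
  rep <- gpm_function(ph$models, ctl_study0(), method_label = "truth")
  expect_lt(abs(rep$edv_ul / ph$true_edv - 1), 0.005)
  expect_lt(abs(rep$esv_ul / ph$true_esv - 1), 0.005)
  expect_lt(abs(rep$lvm_mg / ph$true_mass - 1), 0.005)
})

test_that("strong second-derivative smoothing contracts radial variation", {
  st <- ctl_study0()
  gps <- contours_to_guidepoints(st)
  gps <- gps[gps$frame == 1L, ]
  fit_var <- function(a2) {
    cfg <- fit_config(alpha2 = a2)
    ell <- initial_model(st, cfg)
    # spherical reference: constant radial fields at the mean radii
    init <- lv_surface_model(
      ell$axis_origin, ell$axis_direction, ell$axis_u, ell$axis_v,
      matrix(mean(ell$coeffs_endo), nrow(ell$coeffs_endo),
             ncol(ell$coeffs_endo)),
      matrix(mean(ell$coeffs_epi), nrow(ell$coeffs_epi),
             ncol(ell$coeffs_epi)),
      basis_order = cfg$basis_order)
    m <- suppressMessages(fit_surfaces(gps, init, cfg))$models[[1L]]
    g <- expand.grid(mu = seq(0.2, 0.95, length.out = 24L),
                     th = seq(0, 2 * pi, length.out = 25L)[-25L])
    stats::var(surface_lambda(m, "endo", g$mu, g$th))
  }
  expect_lt(fit_var(1e4), fit_var(0.01))
})

test_that("the fitting objective never increases across outer iterations", {
  set.seed(31)
  for (rep in 1:20) {
    a <- 1.5 + runif(1); cc <- 3 + runif(1)
    truth <- model_from_lambda(ellipsoid_lambda(a, a, cc),
                               ellipsoid_lambda(a + 1, a + 1, cc + 1))
    g <- expand.grid(mu = seq(0.1, 0.95, length.out = 12L),
                     th = seq(0, 2 * pi, length.out = 9L)[-9L])
    pts <- surface_point(truth, "endo", g$mu, g$th) +
      matrix(rnorm(3L * nrow(g), 0, 0.05), ncol = 3L)
    gps <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      surface = "endo", frame = 1L, weight = 1, slice = 1L)
    gps <- rbind(gps, transform(gps, x = x * 1.3, y = y * 1.3, z = z * 1.2,
                                surface = "epi"))
    cfg <- fit_config(basis_order = c(6L, 8L))
    init <- model_from_lambda(ellipsoid_lambda(a * 1.1, a * 1.1, cc * 0.9),
                              ellipsoid_lambda(a * 1.1 + 1, a * 1.1 + 1,
                                               cc * 0.9 + 1),
                              basis_order = c(6L, 8L))
    fit <- suppressMessages(fit_surfaces(gps, init, cfg))
    for (tr in fit$diagnostics[[1L]]$objective)
      if (length(tr) > 1L) expect_true(all(diff(tr) <= 1e-9))
    expect_gte(fit$diagnostics[[1L]]$iterations, 1L)
  }
})

test_that("fitted volumes are invariant under rigid rotation of the study", {
  st <- ctl_study0()
  sub <- function(study) { study$n_frames <- study$n_frames; study }
  # restrict to 2 frames for speed
  shrink <- function(study) {
    study$slices <- lapply(study$slices, function(s) {
      s$endo <- s$endo[1:2]; s$epi <- s$epi[1:2]; s
    })
    study$mv_points <- study$mv_points[1:2]
    study$n_frames <- 2L
    study
  }
  s0 <- shrink(st)
  R <- rot_xyz(0.4, -0.7, 1.1)
  s1 <- rotate_study(s0, R)
  r0 <- analyze_gpm(s0, "full")$report
  r1 <- analyze_gpm(s1, "full")$report
  expect_equal(r1$edv_ul, r0$edv_ul, tolerance = 1e-6)
  expect_equal(r1$lvm_mg, r0$lvm_mg, tolerance = 1e-6)
})

test_that("missing guide points for a surface name the offending frame", {
  st <- ctl_study0()
  gps <- contours_to_guidepoints(st)
  gps <- gps[gps$frame == 1L & gps$surface == "endo", ]
  cfg <- fit_config()
  expect_error(fit_surfaces(gps, initial_model(st, cfg), cfg),
               "no epi guide points for frame 1")
})

test_that("reduced-slice protocols stay close to truth on symmetric phantoms", {
  ph <- ctl_phantom()
  for (p in c("six", "four")) {
    rep <- analyze_gpm(ctl_study0(), p)$report
    expect_lt(abs(rep$edv_ul / ph$true_edv - 1), 0.05)
    expect_lt(abs(rep$lvm_mg / ph$true_mass - 1), 0.05)
    expect_equal(rep$method_label, paste0("gpm_", p))
  }
})
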