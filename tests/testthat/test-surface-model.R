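test_that("constant radial field gives a sphere; ellipsoid hits its semi-axes", {
  sph <- model_from_lambda(function(mu, th) rep(2, length(mu)),
                           function(mu, th) rep(2.6, length(mu)),
                           axis_origin = c(1, -1, 0.5))
  g <- expand.grid(mu = seq(0, 1, by = 0.1), th = seq(0, 2 * pi, by = 0.5))
  pts <- surface_point(sph, "endo", g$mu, g$th)
  expect_equal(sqrt(rowSums(sweep(pts, 2L, c(1, -1, 0.5))^2)),
               rep(2, nrow(g)), tolerance = 1e-9)

  ell <- model_from_lambda(ellipsoid_lambda(1.5, 2.0, 4.0),
                           ellipsoid_lambda(2.5, 3.0, 5.0),
                           axis_direction = c(0, 0, -1),
                           axis_u = c(1, 0, 0), axis_v = c(0, 1, 0),
                           basis_order = c(16L, 24L))
  # equator, theta = 0: exactly along +axis_u, radius to basis accuracy
  p_eq <- drop(surface_point(ell, "endo", 0.5, 0))
  expect_equal(p_eq[2:3], c(0, 0), tolerance = 1e-9)
  expect_equal(p_eq[1], 1.5, tolerance = 2e-3)
  p_v <- drop(surface_point(ell, "endo", 0.5, pi / 2))
  expect_equal(p_v[c(1, 3)], c(0, 0), tolerance = 1e-9)
  expect_equal(p_v[2], 2.0, tolerance = 2e-3)
  # base pole (mu = 0) lies at +c along the axis whatever theta
  p_pole <- drop(surface_point(ell, "endo", 0, 1.3))
  expect_equal(p_pole, c(0, 0, 4.0), tolerance = 2e-3)
})

test_that("surface_lambda matches an independently coded basis expansion", {
  set.seed(11)
  k_mu <- 6L; k_th <- 8L
  ce <- matrix(2 + 0.3 * rnorm(k_mu * k_th), k_mu, k_th)
  m <- lv_surface_model(c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
                        ce, ce + 1, basis_order = c(k_mu, k_th))
  # naive evaluator: explicit double loop over the coefficient grid with
  # scalar spline evaluations and hand-rolled periodic wrapping
  naive <- function(C, mu, th) {
    knots_mu <- c(rep(0, 4), seq_len(k_mu - 4) / (k_mu - 3), rep(1, 4))
    h <- 2 * pi / k_th
    th <- th %% (2 * pi)
    tot <- 0
    for (i in seq_len(k_mu)) {
      bi <- splines::splineDesign(knots_mu, mu, ord = 4)[, i]
      for (j in seq_len(k_th)) {
        pj <- 0
        for (rep_k in -1:1) {  # periodic images of basis j
          kn <- (j - 4 + rep_k * k_th) * h + (0:4) * h
          if (th >= kn[1] && th < kn[5])
            pj <- pj + splines::splineDesign(kn, th, ord = 4, outer.ok = TRUE)
        }
        tot <- tot + C[i, j] * bi * pj
      }
    }
    tot
  }
  for (p in list(c(0.23, 1.1), c(0.77, 5.9), c(0.5, 0.1))) {
    expect_equal(surface_lambda(m, "endo", p[1], p[2]),
                 as.numeric(naive(m$coeffs_endo, p[1], p[2])),
                 tolerance = 1e-10)
  }
})

test_that("surfaces are theta-periodic, apex-closed and smooth", {
  set.seed(3)
  ce <- matrix(2.5 + 0.4 * rnorm(48), 6L, 8L)
  m <- lv_surface_model(c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
                        ce, ce + 0.8, basis_order = c(6L, 8L))
  mu <- seq(0.05, 0.95, by = 0.05)
  expect_equal(surface_lambda(m, "endo", mu, rep(0, length(mu))),
               surface_lambda(m, "endo", mu, rep(2 * pi, length(mu))),
               tolerance = 1e-12)
  expect_equal(surface_lambda(m, "endo", mu, rep(0, length(mu)), dth = 1L),
               surface_lambda(m, "endo", mu, rep(2 * pi, length(mu)), dth = 1L),
               tolerance = 1e-10)
  # apex closed: one well-defined point whatever theta
  apex <- surface_point(m, "endo", rep(1, 7), seq(0, 2 * pi, length.out = 7))
  expect_lt(max(dist(apex)), 1e-12)
  # smoothness: finite-difference second derivatives bounded
  h <- 1e-4
  d2 <- (surface_lambda(m, "endo", mu + h, mu * 0 + 1) -
           2 * surface_lambda(m, "endo", mu, mu * 0 + 1) +
           surface_lambda(m, "endo", mu - h, mu * 0 + 1)) / h^2
  expect_true(all(is.finite(d2)) && max(abs(d2)) < 1e3)
  expect_error(surface_lambda(m, "endo", 1.2, 0), "mu")
})

test_that("model validation enforces positivity and epi outside endo", {
  ce <- matrix(2, 4L, 8L)
  m_bad <- lv_surface_model(c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
                            ce, ce - 0.5, basis_order = c(4L, 8L))
  expect_error(validate_lv_surface_model(m_bad), "crosses inside")
  m_ok <- lv_surface_model(c(0, 0, 0), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
                           ce, ce + 0.5, basis_order = c(4L, 8L))
  expect_silent(validate_lv_surface_model(m_ok))
})
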