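# Shared fixtures, built once per test run.  Phantoms use 8 frames (end-
# systole falls exactly at mid-cycle) to keep the suite fast; the full
# 20-frame studies are exercised by the acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

ctl_phantom <- function()
  cached("ctl", make_phantom(phantom_spec(n_frames = 8L)))

ctl_study0 <- function()   # noise-free acquisition
  cached("ctl_study0", acquire_study(ctl_phantom(), noise_sd_mm = 0))

inf_phantom <- function() {
  cached("inf", {
    spec <- phantom_preset("infarct")
    spec$n_frames <- 8L
    make_phantom(spec)
  })
}

# minimal synthetic study: n_sax circular SAX slices (shrinking toward the
# apex) plus two LAX slices, 2 frames, for slice-bookkeeping tests
toy_study <- function(n_sax = 9L, n_frames = 2L, r_base = 2) {
  circle <- function(r, n = 24L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(r * cos(th), r * sin(th))
  }
  slices <- lapply(seq_len(n_sax), function(k) {
    r <- r_base * sqrt(1 - ((k - 0.5) / n_sax)^2)
    pl <- slice_plane(c(0, 0, -(k - 1)), c(0, 0, -1), c(1, 0, 0), c(0, -1, 0),
                      slice_label = "SAX", sax_index = k)
    list(plane = pl,
         endo = lapply(seq_len(n_frames), function(f) circle(r * (1 - 0.1 * (f - 1)))),
         epi = lapply(seq_len(n_frames), function(f) circle(r + 0.5)))
  })
  for (lab in c("LAX_2CH", "LAX_4CH")) {
    u <- if (lab == "LAX_2CH") c(1, 0, 0) else c(0, 1, 0)
    pl <- slice_plane(c(0, 0, 0), vcross_test(u, c(0, 0, -1)), u, c(0, 0, 1),
                      slice_label = lab)
    slices[[length(slices) + 1L]] <-
      list(plane = pl,
           endo = rep(list(circle(1.5)), n_frames),
           epi = rep(list(circle(2)), n_frames))
  }
  mv <- rep(list(rbind(c(1.5, 0, 0.5), c(-1.5, 0, 0.5),
                       c(0, 1.5, 0.5), c(0, -1.5, 0.5))), n_frames)
  cine_study(slices, mv, n_frames, slice_thickness_mm = 1,
             pixel_size_mm = 0.05, meta = list(animal_id = "toy"))
}

vcross_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rigid rotation of a study about the origin
rotate_study <- function(study, R) {
  rot_plane <- function(p)
    slice_plane(drop(R %*% p$origin), drop(R %*% p$normal),
                drop(R %*% p$axis_u), drop(R %*% p$axis_v),
                slice_label = p$slice_label, sax_index = p$sax_index)
  study$slices <- lapply(study$slices, function(s) {
    s$plane <- rot_plane(s$plane)
    s
  })
  study$mv_points <- lapply(study$mv_points, function(m) m %*% t(R))
  study
}

rot_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
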