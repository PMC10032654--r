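test_that("resampling interpolates keyframes and blends between them", {
  trk <- simulate_swimmer(swimmer_spec(duration = 0.2))
  rs <- resample_midline(trk, n_out = 41, keyframe_stride = 6)
  expect_equal(length(unique(rs$marker)), 41)
  # the resampled curve passes through the raw markers at a keyframe
  raw0 <- trk[trk$frame == 0, ]
  st0 <- rs[rs$frame == 0, ]
  for (k in seq_len(nrow(raw0))) {
    d <- sqrt((st0$x_m - raw0$x_m[k])^2 + (st0$y_m - raw0$y_m[k])^2)
    expect_lt(min(d), 2e-4) # within the dense station spacing
  }
  # a frame midway between keyframes is the mean of the bracketing stations
  mid <- rs[rs$frame == 3, c("x_m", "y_m")]
  a <- rs[rs$frame == 0, c("x_m", "y_m")]
  b <- rs[rs$frame == 6, c("x_m", "y_m")]
  expect_equal(as.matrix(mid), (as.matrix(a) + as.matrix(b)) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a straight midline resamples to collinear, equally spaced stations", {
  d <- tidyr::expand_grid(frame = 0:11, marker = 0:8)
  d$time_s <- d$frame / 125
  d$x_m <- d$marker * 0.19 / 8
  d$y_m <- 0.5 * d$x_m
  trk <- midline_track(d)
  rs <- resample_midline(trk, n_out = 21)
  st <- rs[rs$frame == 6, ]
  expect_equal(st$y_m, 0.5 * st$x_m, tolerance = 1e-9)
  gaps <- sqrt(diff(st$x_m)^2 + diff(st$y_m)^2)
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-6)
})

test_that("tail-beat frequency is recovered and degenerate input errors", {
  trk <- simulate_swimmer(swimmer_spec(f = 2, duration = 2.5))
  rs <- resample_midline(trk, n_out = 21, keyframe_stride = 6)
  expect_equal(tailbeat_frequency(rs), 2, tolerance = 0.01)
  # constant track: no oscillation
  d <- tidyr::expand_grid(frame = 0:200, marker = 0:8)
  d$time_s <- d$frame / 125
  d$x_m <- d$marker * 0.19 / 8
  d$y_m <- 0
  expect_error(tailbeat_frequency(midline_track(d)), "oscillate")
  # too short for three cycles
  short <- simulate_swimmer(swimmer_spec(f = 2, duration = 1.2))
  expect_error(tailbeat_frequency(short), "insufficient cycles")
})

test_that("follower frequency matches the wake shedding rate end to end", {
  wk <- wake_spec(n_frames = 1)
  fol <- simulate_inline_follower(wk, swimmer_spec(duration = 2.5), 0.1)
  f_hat <- tailbeat_frequency(fol$track[[1]])
  expect_equal(f_hat, wk$U_c / wk$lam_w, tolerance = 0.02 * 2)
})

test_that("joint angles vanish for straight bodies and equal theta/N on arcs", {
  mk <- function(xy) {
    d <- tidyr::expand_grid(frame = 0:3, k = seq_len(nrow(xy)))
    d$time_s <- d$frame / 125
    d$marker <- d$k - 1L
    d$x_m <- xy[d$k, 1]; d$y_m <- xy[d$k, 2]
    midline_track(d[, c("frame", "time_s", "marker", "x_m", "y_m")])
  }
  s <- seq(0, 0.19, length.out = 25)
  straight <- mk(cbind(s, 0))
  ja <- joint_angles(straight, 20)
  expect_true(all(abs(ja$angle_rad) < 1e-9))
  # rigid rotation leaves relative angles at zero
  th <- 0.6
  rot <- mk(cbind(s * cos(th), s * sin(th)))
  expect_true(all(abs(joint_angles(rot, 20)$angle_rad) < 1e-9))
  # circular arc of total tangent turning theta: each joint angle theta/N
  theta <- 0.8; R <- 0.19 / theta
  a <- seq(0, theta, length.out = 41)
  arc <- mk(cbind(R * sin(a), R * (1 - cos(a))))
  ja_arc <- joint_angles(arc, 20)
  expect_equal(abs(ja_arc$angle_rad), rep(theta / 20, nrow(ja_arc)),
               tolerance = 1e-3)
  expect_error(joint_angles(straight, 30), "n_segments \\+ 1")
})

test_that("phase lags recover the body wavelength for traveling waves", {
  for (lam in c(0.5, 1.0)) {
    trk <- simulate_swimmer(sweep_swimmer(2, lam, duration = 2.5))
    rs <- resample_midline(trk, n_out = 33, keyframe_stride = 1)
    pl <- phase_lags(joint_angles(rs), T = 0.5)
    expect_equal(pl$overall, 2 * pi / lam, tolerance = 0.02 * 2 * pi / lam)
    # definition identity: wavelength * overall = 2 pi
    expect_equal(pl$wavelength_bl * pl$overall, 2 * pi)
    expect_equal(sum(pl$delta_phi), pl$overall)
  }
})

test_that("a standing wave has zero overall phase lag", {
  # all joints oscillate in phase: y(s, t) = A s^2 sin(2 pi f t)
  frames <- 0:374
  d <- tidyr::expand_grid(frame = frames, marker = 0:20)
  d$time_s <- d$frame / 125
  s <- d$marker / 20
  d$x_m <- s * 0.19
  d$y_m <- 0.01 * s^2 * sin(2 * pi * 2 * d$time_s)
  trk <- midline_track(d, body_length = 0.19, fps = 125)
  pl <- phase_lags(joint_angles(trk), T = 0.5)
  expect_lt(pl$overall, 0.1)
  expect_equal(pl$wavelength_bl, Inf)
})

test_that("phase lag rejects zero-variance angle signals", {
  d <- tidyr::expand_grid(frame = 0:374, marker = 0:20)
  d$time_s <- d$frame / 125
  d$x_m <- d$marker * 0.19 / 20
  d$y_m <- 0
  trk <- midline_track(d, body_length = 0.19, fps = 125)
  expect_error(phase_lags(joint_angles(trk), T = 0.5), "zero-variance")
})

test_that("amplitude profiles recover the envelope and ignore heading", {
  sp <- swimmer_spec(duration = 2, a_head = 0.003, a_tail = 0.019)
  prof <- amplitude_profile(simulate_swimmer(sp))
  expect_equal(prof$amplitude_m[nrow(prof)], 0.019, tolerance = 0.02 * 0.019)
  expect_true(all(prof$amplitude_m >= 0))
  # rigid 30 degree rotation: identical profile within 1%
  sp_rot <- sp; sp_rot$heading <- 30 * pi / 180
  prof_rot <- amplitude_profile(simulate_swimmer(sp_rot))
  expect_equal(prof_rot$amplitude_m, prof$amplitude_m,
               tolerance = 0.01)
  # zero lateral motion
  sp0 <- swimmer_spec(a_head = 0, a_tail = 1e-15, duration = 2)
  prof0 <- amplitude_profile(simulate_swimmer(sp0))
  expect_true(all(prof0$amplitude_m < 1e-10))
})

test_that("kinematic outputs are invariant under rigid transforms", {
  base <- swimmer_spec(f = 2, lam = 1.0, duration = 2.5, n_markers = 33)
  moved <- base
  moved$heading <- 0.7
  moved$snout_offset <- c(0.4, -0.2)
  r1 <- resample_midline(simulate_swimmer(base), 33, 1)
  r2 <- resample_midline(simulate_swimmer(moved), 33, 1)
  expect_equal(tailbeat_frequency(r2), tailbeat_frequency(r1),
               tolerance = 1e-6)
  pl1 <- phase_lags(joint_angles(r1), T = 0.5)
  pl2 <- phase_lags(joint_angles(r2), T = 0.5)
  expect_equal(pl2$overall, pl1$overall, tolerance = 1e-3)
  a1 <- amplitude_profile(r1); a2 <- amplitude_profile(r2)
  expect_equal(a2$amplitude_m, a1$amplitude_m, tolerance = 1e-4)
})

test_that("noisy digitisation still recovers frequency and phase lag", {
  # 1 mm tracking noise on a 0.19 m fish, smoothed digitisation pipeline
  sp <- sweep_swimmer(2, 1.0, noise_sd = 0.001, seed = 42, duration = 4)
  rs <- resample_midline(simulate_swimmer(sp), 33, 1, smooth = TRUE)
  f_hat <- tailbeat_frequency(rs)
  expect_equal(f_hat, 2, tolerance = 0.02)
  pl <- phase_lags(joint_angles(rs), T = 1 / f_hat)
  expect_equal(pl$overall, 2 * pi, tolerance = 0.05 * 2 * pi)
})

test_that("the tail-growing envelope shifts the joint-angle phase gradient", {
  # with a quadratic tail-growing envelope the true overall lag of the
  # joint-angle wave differs from 2 pi / lam by a few percent: the envelope's
  # arclength derivative mixes into the wave phase. The pipeline measures
  # that modified gradient; this documents the effect size at the defaults.
  trk <- simulate_swimmer(swimmer_spec(f = 2, lam = 1.0, duration = 2.5,
                                       n_markers = 33))
  rs <- resample_midline(trk, 33, 1)
  pl <- phase_lags(joint_angles(rs), T = 0.5)
  expect_lt(abs(pl$overall - 2 * pi) / (2 * pi), 0.06)
  expect_gt(abs(pl$overall - 2 * pi) / (2 * pi), 0.01)
})

test_that("phase differences follow delays and unwrap across followers", {
  t <- seq(0, 3, by = 1 / 125)
  base <- tibble::tibble(time_s = t, y = sin(2 * pi * 2 * t))
  expect_equal(phase_difference(base, base, T = 0.5), 0, tolerance = 1e-6)
  delayed <- tibble::tibble(time_s = t, y = sin(2 * pi * 2 * (t - 0.125)))
  expect_equal(phase_difference(base, delayed, T = 0.5), pi / 2,
               tolerance = 0.01)
  short <- base[base$time_s < 1, ]
  expect_error(phase_difference(base, short, T = 0.5), "3 shared cycles")
})

test_that("gap distance is Euclidean and rigid-transform invariant", {
  expect_equal(gap_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(gap_distance(c(0, 0), c(0.3, 0)), 0.3)
  a <- c(0.1, 0.2); b <- c(0.4, -0.1)
  th <- 0.9; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(gap_distance(as.vector(R %*% a) + 1, as.vector(R %*% b) + 1),
               gap_distance(a, b))
  # matrix input: mean positions over a window
  expect_equal(gap_distance(rbind(c(0, 0), c(0.2, 0)), c(0.4, 0)), 0.3)
})
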