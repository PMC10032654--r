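test_that("swimmer tracks honour the digitisation layout and determinism", {
  sp <- swimmer_spec(duration = 1, noise_sd = 1e-4, seed = 7)
  trk <- simulate_swimmer(sp)
  expect_s3_class(trk, "midline_track")
  expect_equal(n_distinct_markers <- length(unique(trk$marker)), 9)
  expect_equal(track_fps(trk), 125)
  expect_identical(simulate_swimmer(sp), trk) # seeded determinism
  sp2 <- sp; sp2$seed <- 8
  expect_false(identical(simulate_swimmer(sp2)$y_m, trk$y_m))
  expect_error(swimmer_spec(fps = 3, f = 2), "aliasing")
  expect_error(swimmer_spec(a_head = 0.02, a_tail = 0.01), "a_tail >= a_head")
})

test_that("tail marker lateral half-range equals the tail amplitude", {
  sp <- swimmer_spec(duration = 2, a_tail = 0.015)
  trk <- simulate_swimmer(sp)
  tail <- trk[trk$marker == 8, ]
  expect_equal(diff(range(tail$y_m)) / 2, 0.015, tolerance = 1e-3)
})

test_that("marker arclengths are time-invariant (inextensible body)", {
  trk <- simulate_swimmer(swimmer_spec(duration = 1))
  lens <- vapply(split(trk, trk$frame), function(d) {
    sum(sqrt(diff(d$x_m)^2 + diff(d$y_m)^2))
  }, numeric(1))
  # the body arclength is exactly conserved; the marker-chain chord length
  # varies only through curvature-dependent chord shortening (~0.1%)
  expect_lt(diff(range(lens)) / mean(lens), 5e-3)
})

test_that("wake spec validates its geometry", {
  expect_error(wake_spec(r_c = 0.05, b = 0.04), "core radius")
  expect_error(wake_spec(grid = list(x = c(0, 0.4), y = c(-0.1, 0.1),
                                     h = 0.01)), "coarse")
  expect_error(wake_spec(street_sign = 2), "street_sign")
})

test_that("zero-circulation wake is the undisturbed free stream", {
  wk <- simulate_wake(wake_spec(gamma = 0, n_frames = 2))
  expect_true(all(abs(wk$u - 0.3) < 1e-12))
  expect_true(all(abs(wk$v) < 1e-12))
})

test_that("street sign controls the centerline jet/deficit dichotomy", {
  # one shedding period: lam_w / U_c = 0.5 s at the defaults
  thrust <- simulate_wake(wake_spec(fps = 50, n_frames = 26))
  drag <- simulate_wake(wake_spec(fps = 50, n_frames = 26, street_sign = -1))
  expect_gt(centerline_mean_u(thrust), 0.3)
  expect_lt(centerline_mean_u(drag), 0.3)
  # flipping the sign mirrors the excess
  expect_equal(centerline_mean_u(thrust) - 0.3, 0.3 - centerline_mean_u(drag),
               tolerance = 1e-9)
})

test_that("vortex centers are recovered with alternating signs at lam_w spacing", {
  ws <- wake_spec(n_frames = 1)
  wk <- simulate_wake(ws)
  vc <- vortex_centers(wk, 1)
  # compare in the interior where cores are fully resolved (edge vortices
  # have clipped blobs and biased centroids)
  inner <- c(min(wk$x) + 3 * ws$r_c, max(wk$x) - 3 * ws$r_c)
  truth <- attr(wk, "centers")[[1]]
  truth <- truth[truth$x >= inner[1] & truth$x <= inner[2], ]
  vc <- vc[vc$x_m >= inner[1] & vc$x_m <= inner[2], ]
  expect_equal(nrow(vc), nrow(truth))
  expect_true(all(abs(diff(vc$sign)) == 2)) # alternating downstream
  same_row <- diff(vc$x_m, lag = 2)         # within-row spacing
  expect_true(all(abs(same_row - ws$lam_w) <= ws$grid$h))
  # each detected center within one cell of a true vortex
  for (i in seq_len(nrow(vc))) {
    d <- sqrt((truth$x - vc$x_m[i])^2 + (truth$y - vc$y_m[i])^2)
    expect_lt(min(d), sqrt(2) * ws$grid$h)
  }
})

test_that("analytic flows carry their defining structure", {
  g <- unit_grid()
  un <- analytic_flow("uniform", list(U = 0.4), g)
  expect_equal(un$u[, , 1], un$u[, , 2]) # steady
  expect_true(all(un$u == 0.4) && all(un$v == 0))
  sr <- analytic_flow("solid_rotation", list(Omega = 3), g)
  i <- 26; j <- 51 # a node at known radius
  r <- sqrt(sr$x[i]^2 + sr$y[j]^2)
  expect_equal(sqrt(sr$u[i, j, 1]^2 + sr$v[i, j, 1]^2), 3 * r,
               tolerance = 1e-12)
  # Lamb-Oseen azimuthal speed peaks at ~1.12 r_c (independent 1-D oracle)
  r_c <- 0.1
  vth <- function(r) 0.01 / (2 * pi * r) * (1 - exp(-r^2 / r_c^2))
  r_star <- stats::optimize(vth, c(0.02, 0.5), maximum = TRUE)$maximum
  expect_equal(r_star / r_c, 1.12, tolerance = 0.01)
  lo <- analytic_flow("lamb_oseen", list(gamma = 0.01, r_c = r_c), g)
  speeds <- sqrt(lo$u[, 51, 1]^2 + lo$v[, 51, 1]^2)
  expect_lt(abs(abs(lo$x[which.max(speeds)]) - r_star), g$h)
  expect_error(analytic_flow("weird", list(), g), "arg")
})

test_that("body masks rasterise the width envelope", {
  g <- list(x = c(0, 0.4), y = c(-0.1, 0.1), h = 0.0025)
  wk <- analytic_flow("uniform", list(U = 0.3), g)
  midl <- tibble::tibble(x_m = seq(0.1, 0.3, length.out = 9), y_m = 0)
  empty <- body_mask(midl, width = 0, wk)
  expect_equal(dim(empty), c(length(wk$x), length(wk$y)))
  expect_false(any(empty))
  w <- 0.03
  msk <- body_mask(midl, width = w, wk)
  area <- sum(msk) * g$h^2
  # rectangle of length 0.2 and width w (rounded end caps add < w^2)
  expect_lt(abs(area - w * 0.2), 0.1 * w * 0.2 + w^2)
  outside <- tibble::tibble(x_m = c(-0.5, 0.5), y_m = c(0, 0))
  expect_error(body_mask(outside, 0.03, wk), "outside")
})

test_that("wake-locked followers are phased by vortex transit time", {
  wk <- wake_spec(n_frames = 1)
  sw <- swimmer_spec(duration = 2)
  expect_error(simulate_inline_follower(wk, sw, numeric(0)), "empty")
  d <- c(0, 0.05, 0.1, 0.15)
  fol <- simulate_inline_follower(wk, sw, d, phase_const = 0.3)
  specs <- lapply(fol$track, attr, "source_spec")
  ph <- vapply(specs, function(s) s$phase0, numeric(1))
  # exactly linear in distance with slope -2 pi / lam_w (delay convention)
  expect_equal(diff(ph) / diff(d), rep(-2 * pi / wk$lam_w, 3),
               tolerance = 1e-12)
  expect_equal(ph[1], 0.3) # d = 0 leaves only the constant
  expect_equal(vapply(specs, function(s) s$f, numeric(1)),
               rep(wk$U_c / wk$lam_w, 4))
  # mean snout position sits at the requested gap distance on the centerline
  snout <- fol$track[[3]][fol$track[[3]]$marker == 0, ]
  expect_equal(mean(snout$x_m), 0.1, tolerance = 1e-6)
  expect_lt(abs(mean(snout$y_m)), 1e-4)
})
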