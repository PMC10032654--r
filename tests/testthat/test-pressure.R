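test_that("pressure gradients vanish in steady uniform flow", {
  fl <- analytic_flow("uniform", list(U = 0.3), unit_grid())
  g <- pressure_gradient(fl, 1, pressure_config())
  expect_true(all(abs(g$dpdx) < 1e-12))
  expect_true(all(abs(g$dpdy) < 1e-12))
  one_frame <- vf_seq(fl$x, fl$y, fl$u[, , 1], fl$v[, , 1], dt = fl$dt)
  expect_error(pressure_gradient(one_frame, 1, pressure_config()),
               "two sequential")
})

test_that("solid-rotation gradient is rho Omega^2 r, outward", {
  rho <- 1000; Om <- 2
  fl <- analytic_flow("solid_rotation", list(Omega = Om), unit_grid(),
                      rho = rho)
  g <- pressure_gradient(fl, 1, pressure_config(rho = rho))
  X <- matrix(fl$x, 101, 101); Y <- matrix(fl$y, 101, 101, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  mag <- sqrt(g$dpdx^2 + g$dpdy^2)
  interior <- R > 0.1 & abs(X) < 0.9 & abs(Y) < 0.9
  expect_lt(max(abs(mag[interior] - rho * Om^2 * R[interior]) /
                  (rho * Om^2 * R[interior])), 0.02)
  # points outward, from low to high pressure
  radial <- (g$dpdx * X + g$dpdy * Y) / pmax(R, 1e-9)
  expect_true(all(radial[interior] > 0))
})

test_that("Lamb-Oseen radial gradient matches rho v^2 / r", {
  rho <- 1000
  fl <- analytic_flow("lamb_oseen", list(gamma = 0.01, r_c = 0.1),
                      unit_grid(), rho = rho)
  g <- pressure_gradient(fl, 1, pressure_config(rho = rho))
  X <- matrix(fl$x, 101, 101); Y <- matrix(fl$y, 101, 101, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  vth <- 0.01 / (2 * pi * pmax(R, 1e-9)) * (1 - exp(-R^2 / 0.1^2))
  want <- rho * vth^2 / pmax(R, 1e-9)
  mag <- sqrt(g$dpdx^2 + g$dpdy^2)
  sel <- R > 2 * 0.02 & abs(X) < 0.9 & abs(Y) < 0.9
  expect_lt(max(abs(mag[sel] - want[sel]) / pmax(want[sel], 1e-9)), 0.05)
})

test_that("zero gradient integrates to zero pressure everywhere", {
  z <- matrix(0, 41, 41)
  grad <- structure(list(dpdx = z, dpdy = z,
                         x = seq(0, 1, length.out = 41),
                         y = seq(0, 1, length.out = 41),
                         mask = NULL, h = 0.025),
                    class = "pressure_gradient")
  pf <- integrate_pressure(grad)
  expect_true(all(abs(pf$p) < 1e-12))
  expect_true(all(pf$defined))
  expect_error(integrate_pressure(grad, mask = matrix(TRUE, 41, 41)),
               "masked")
})

test_that("median polling reconstructs conservative pressure differences", {
  rho <- 1000
  fl <- analytic_flow("solid_rotation", list(Omega = 2), unit_grid(),
                      rho = rho)
  pf <- integrate_pressure(pressure_gradient(fl, 1, pressure_config(rho = rho)))
  p_true <- p_solid_rotation(fl$x, fl$y, 2, rho)
  expect_lt(rms_of_range(pf$p, p_true), 0.005)
})

test_that("solid nodes stay undefined and enclosed nodes fill from neighbours", {
  n <- 21
  z <- matrix(0, n, n)
  solid <- matrix(FALSE, n, n)
  solid[9:13, 9:13] <- TRUE
  solid[11, 11] <- FALSE # fluid node enclosed on all eight directions
  grad <- structure(list(dpdx = z, dpdy = z,
                         x = seq(0, 1, length.out = n),
                         y = seq(0, 1, length.out = n),
                         mask = solid, h = 1 / (n - 1)),
                    class = "pressure_gradient")
  pf <- integrate_pressure(grad)
  expect_true(all(is.na(pf$p[solid])))
  expect_false(pf$defined[10, 10])
  # the enclosed node is filled from the nearest defined fluid node
  expect_false(pf$defined[11, 11])
  expect_equal(pf$p[11, 11], 0)
})

test_that("median aggregation resists a corrupted path family", {
  rho <- 1000
  fl <- analytic_flow("lamb_oseen", list(gamma = 0.01, r_c = 0.1),
                      unit_grid(), rho = rho)
  g <- pressure_gradient(fl, 1, pressure_config(rho = rho))
  solid <- matrix(FALSE, 101, 101)
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  fams <- lapply(dirs, function(d) {
    thrustwake:::family_field(g$dpdx, g$dpdy, solid, g$h, d[1], d[2])
  })
  clean <- simplify2array(fams)
  corrupt <- clean
  noise_scale <- diff(range(clean[, , 1]))
  set.seed(11)
  corrupt[, , 3] <- corrupt[, , 3] + stats::rnorm(101 * 101, 0, noise_scale)
  med_shift <- apply(corrupt, c(1, 2), stats::median) -
    apply(clean, c(1, 2), stats::median)
  mean_shift <- apply(corrupt, c(1, 2), mean) -
    apply(clean, c(1, 2), mean)
  expect_lt(mean(abs(med_shift)), mean(abs(mean_shift)))
})

test_that("gauge shifts leave relative pressures unchanged", {
  rho <- 1000
  fl <- analytic_flow("lamb_oseen", list(gamma = 0.01, r_c = 0.1),
                      unit_grid(), rho = rho)
  g <- pressure_gradient(fl, 1, pressure_config(rho = rho))
  pf1 <- integrate_pressure(g)
  # re-gauge by an arbitrary constant: differences identical
  shifted <- pf1$p + 3.7
  d1 <- pf1$p[30, 40] - pf1$p[70, 20]
  d2 <- shifted[30, 40] - shifted[70, 20]
  expect_equal(d1, d2)
})

test_that("head pressure averages the snout box and reports forces", {
  x <- seq(0, 0.4, by = 0.0025); y <- seq(-0.1, 0.1, by = 0.0025)
  p0 <- matrix(2.5, length(x), length(y))
  pf <- structure(list(x = x, y = y, p = p0,
                       defined = matrix(TRUE, length(x), length(y))),
                  class = "pressure_field")
  # uniform field: mean is the constant; zero field gives zero
  hp <- head_pressure(pf, snout = c(0.1, 0), heading = pi, BL = 0.158,
                      width = 0.03, S = 2e-4)
  expect_equal(as.numeric(hp), 2.5)
  expect_equal(attr(hp, "force_n"), 2.5 * 2e-4)
  pf0 <- pf; pf0$p[] <- 0
  expect_equal(as.numeric(head_pressure(pf0, c(0.1, 0), pi, 0.158, 0.03)), 0)
  # box rasterisation: node count ~ area / cell area within one cell row
  grid <- expand.grid(x = x, y = y)
  ax <- c(1, 0) # backward direction for heading = pi
  inside <- (grid$x - 0.1) >= 0 & (grid$x - 0.1) <= 0.1 * 0.158 &
    abs(grid$y) <= 0.015
  want <- (0.1 * 0.158 * 0.03) / 0.0025^2
  expect_lt(abs(sum(inside) - want), (0.1 * 0.158 + 0.03) / 0.0025 + 4)
  expect_error(head_pressure(pf, c(10, 10), pi, 0.158, 0.03), "outside")
})

test_that("mean-flow subtraction zeroes u and preserves curl", {
  wk <- simulate_wake(wake_spec(n_frames = 3, fps = 100))
  sub <- subtract_mean_flow(wk)
  expect_lt(abs(mean(sub$u)), 1e-12)
  expect_equal(vorticity(sub, 2), vorticity(wk, 2), tolerance = 1e-9)
  expect_equal(attr(sub, "subtracted_u_mps"), mean(wk$u))
  un <- analytic_flow("uniform", list(U = 0.3), unit_grid())
  expect_true(all(abs(subtract_mean_flow(un)$u) < 1e-12))
  expect_equal(nrow(vortex_centers(un, 1)), 0)
})

test_that("a single vortex is located within one grid cell", {
  g <- list(x = c(-0.2, 0.2), y = c(-0.2, 0.2), h = 0.005)
  lo <- analytic_flow("lamb_oseen",
                      list(gamma = 0.01, r_c = 0.03, center = c(0.04, -0.03)),
                      g)
  vc <- vortex_centers(lo, 1)
  expect_equal(nrow(vc), 1)
  expect_lt(abs(vc$x_m - 0.04), g$h)
  expect_lt(abs(vc$y_m + 0.03), g$h)
  expect_equal(vc$sign, 1)
})
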