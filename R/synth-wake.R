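#' Specification of a synthetic Karman-type vortex street
#'
#' Parameters of a kinematic wake model built from Lamb-Oseen vortices
#' superposed on a uniform free stream: two staggered rows at lateral
#' positions +/- b/2, streamwise spacing `lam_w` within each row, advected
#' downstream at `U_c`. With `street_sign = +1` the circulation signs are
#' arranged as a reverse Karman street (counter-clockwise row on top), which
#' induces a centerline jet: the time-averaged centerline speed exceeds the
#' free stream, the signature of a thrust wake. `street_sign = -1` flips all
#' circulations, giving the classical drag-wake arrangement with a centerline
#' deficit.
#'
#' Vortices are laid out periodically (fresh vortices enter upstream as old
#' ones advect out), so the street is statistically stationary and exactly
#' time-periodic with the shedding period `lam_w / U_c`.
#'
#' Defaults emulate the flapping-foil wake of the study: free stream
#' 0.3 m/s, shedding frequency 2 Hz with advection at 1.1 U_inf (so
#' `lam_w = U_c / f = 0.165 m`), row spacing comparable to the 4 cm
#' trailing-edge excursion.
#'
#' @param gamma Vortex circulation magnitude (m^2/s).
#' @param r_c Lamb-Oseen core radius (m).
#' @param lam_w Streamwise vortex spacing within a row (m).
#' @param b Lateral spacing between the rows (m); must exceed `r_c`.
#' @param U_inf Free-stream speed (m/s).
#' @param U_c Advection speed of the vortices (m/s).
#' @param street_sign `+1` for a reverse (thrust) street, `-1` for a drag
#'   street.
#' @param rho Fluid density (kg/m^3).
#' @param grid List with `x = c(min, max)`, `y = c(min, max)`, `h` spacing
#'   (m); `h` must resolve the core (`h <= r_c / 4`).
#' @param fps Frame rate of the generated sequence (Hz).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed (kept for provenance; the model is
#'   deterministic).
#' @return An object of class `wake_spec`.
#' @export
wake_spec <- function(gamma = 0.008, r_c = 0.01, lam_w = 0.165, b = 0.04,
                      U_inf = 0.3, U_c = 1.1 * U_inf, street_sign = 1,
                      rho = 1000,
                      grid = list(x = c(0, 0.4), y = c(-0.1, 0.1), h = 0.0025),
                      fps = 1000, n_frames = 25, seed = NULL) {
  if (r_c >= b) rlang::abort("core radius `r_c` must be below row spacing `b`")
  if (lam_w <= 0) rlang::abort("`lam_w` must be positive")
  if (!street_sign %in% c(-1, 1)) rlang::abort("`street_sign` must be +1 or -1")
  if (grid$h > r_c / 4) {
    rlang::abort("grid too coarse: need at least 4 cells per core radius")
  }
  structure(list(gamma = gamma, r_c = r_c, lam_w = lam_w, b = b,
                 U_inf = U_inf, U_c = U_c, street_sign = street_sign,
                 rho = rho, grid = grid, fps = fps,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "wake_spec")
}

# Lamb-Oseen induced velocity of one vortex added onto (u, v) matrices
add_lamb_oseen <- function(u, v, X, Y, xc, yc, gamma, r_c) {
  dx <- X - xc; dy <- Y - yc
  r2 <- dx^2 + dy^2
  r2[r2 < 1e-16] <- 1e-16
  k <- gamma / (2 * pi * r2) * (1 - exp(-r2 / r_c^2))
  list(u = u - k * dy, v = v + k * dx)
}

# vortex layout of one frame: positions and circulations
wake_vortices <- function(spec, t) {
  off <- (spec$U_c * t) %% spec$lam_w
  xr <- spec$grid$x
  ks <- seq(floor((xr[1] - 2 * spec$lam_w - off) / spec$lam_w),
            ceiling((xr[2] + 2 * spec$lam_w - off) / spec$lam_w))
  top <- tibble::tibble(x = off + ks * spec$lam_w, y = spec$b / 2,
                        gamma = spec$street_sign * spec$gamma)
  bot <- tibble::tibble(x = off + (ks + 0.5) * spec$lam_w, y = -spec$b / 2,
                        gamma = -spec$street_sign * spec$gamma)
  dplyr::bind_rows(top, bot)
}

#' Simulate a Karman-type vortex-street velocity sequence
#'
#' Evaluates the [wake_spec()] model on its grid for `n_frames` frames at the
#' specified frame rate. The per-frame vortex layout used as ground truth is
#' attached as attribute `centers` (a list of tibbles).
#'
#' @param spec A [wake_spec()].
#' @return A [vf_seq()].
#' @examples
#' wk <- simulate_wake(wake_spec(n_frames = 2))
#' vortex_centers(wk, 1)
#' @export
simulate_wake <- function(spec) {
  stopifnot(inherits(spec, "wake_spec"))
  g <- spec$grid
  x <- seq(g$x[1], g$x[2], by = g$h)
  y <- seq(g$y[1], g$y[2], by = g$h)
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  nt <- spec$n_frames
  u <- array(spec$U_inf, c(length(x), length(y), nt))
  v <- array(0, c(length(x), length(y), nt))
  centers <- vector("list", nt)
  for (fr in seq_len(nt)) {
    t <- (fr - 1) / spec$fps
    vort <- wake_vortices(spec, t)
    uu <- u[, , fr]; vv <- v[, , fr]
    for (i in seq_len(nrow(vort))) {
      res <- add_lamb_oseen(uu, vv, X, Y, vort$x[i], vort$y[i],
                            vort$gamma[i], spec$r_c)
      uu <- res$u; vv <- res$v
    }
    u[, , fr] <- uu; v[, , fr] <- vv
    centers[[fr]] <- vort
  }
  out <- vf_seq(x, y, u, v, dt = 1 / spec$fps,
                U_inf = spec$U_inf, rho = spec$rho)
  attr(out, "centers") <- centers
  attr(out, "source_spec") <- spec
  out
}

#' Time-averaged centerline streamwise speed
#'
#' Mean of `u` over the row of nodes nearest y = 0, averaged over all frames;
#' above `U_inf` for a thrust wake, below for a drag wake.
#'
#' @param seq A [vf_seq()].
#' @return Mean centerline u (m/s).
#' @export
centerline_mean_u <- function(seq) {
  j <- which.min(abs(seq$y))
  mean(seq$u[, j, ])
}

#' Analytic oracle flows
#'
#' Steady flows with closed-form pressure structure, used to validate the
#' pressure-reconstruction chain: `uniform` (constant velocity, constant
#' pressure), `solid_rotation` (v_theta = Omega r, pressure rises as
#' rho Omega^2 r^2 / 2), and a steady `lamb_oseen` vortex (radial pressure
#' gradient rho v_theta(r)^2 / r).
#'
#' @param kind One of `"uniform"`, `"solid_rotation"`, `"lamb_oseen"`.
#' @param params Named list: `U` for uniform; `Omega` and optional `center`
#'   for solid rotation; `gamma`, `r_c`, optional `center` for Lamb-Oseen.
#' @param grid List with `x = c(min, max)`, `y = c(min, max)`, `h` (m).
#' @param n_frames Number of (identical) frames; >= 2 so that time
#'   derivatives can be formed.
#' @param dt Frame interval (s).
#' @param rho Fluid density (kg/m^3).
#' @return A [vf_seq()].
#' @export
analytic_flow <- function(kind, params, grid, n_frames = 2, dt = 1e-3,
                          rho = 1000) {
  kind <- match.arg(kind, c("uniform", "solid_rotation", "lamb_oseen"))
  x <- seq(grid$x[1], grid$x[2], by = grid$h)
  y <- seq(grid$y[1], grid$y[2], by = grid$h)
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  if (kind == "uniform") {
    U <- params$U %||% 1
    u0 <- matrix(U, length(x), length(y))
    v0 <- matrix(0, length(x), length(y))
  } else {
    ctr <- params$center %||% c(mean(grid$x), mean(grid$y))
    dx <- X - ctr[1]; dy <- Y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    r[r < 1e-12] <- 1e-12
    vth <- if (kind == "solid_rotation") {
      params$Omega * r
    } else {
      params$gamma / (2 * pi * r) * (1 - exp(-r^2 / params$r_c^2))
    }
    u0 <- -vth * dy / r
    v0 <- vth * dx / r
  }
  u <- array(u0, c(length(x), length(y), n_frames))
  v <- array(v0, c(length(x), length(y), n_frames))
  vf_seq(x, y, u, v, dt = dt,
         U_inf = if (kind == "uniform") params$U %||% 1 else NA_real_,
         rho = rho)
}

#' Rasterise a body outline around a midline into a solid mask
#'
#' Marks grid nodes solid when they lie within the lateral half-width
#' envelope of the midline polyline (full width `width(s)` at arclength
#' fraction s).
#'
#' @param midline_frame A data frame with columns `x_m`, `y_m`: the ordered
#'   snout-to-tail midline of one frame.
#' @param width Body width profile: a single number (constant full width, m),
#'   a numeric vector per midline point, or a function of arclength fraction
#'   s in \[0, 1\] returning the full width (m).
#' @param seq A [vf_seq()] supplying the grid.
#' @return A logical `nx x ny` matrix, `TRUE` on solid nodes.
#' @export
body_mask <- function(midline_frame, width, seq) {
  stopifnot(inherits(seq, "vf_seq"))
  mx <- midline_frame$x_m; my <- midline_frame$y_m
  if (min(mx) < min(seq$x) || max(mx) > max(seq$x) ||
      min(my) < min(seq$y) || max(my) > max(seq$y)) {
    rlang::abort("midline lies outside the grid bounds")
  }
  # dense resampling of the polyline in arclength
  seg <- sqrt(diff(mx)^2 + diff(my)^2)
  s_raw <- c(0, cumsum(seg))
  total <- s_raw[length(s_raw)]
  if (total <= 0) rlang::abort("degenerate midline (zero length)")
  s_d <- seq(0, total, length.out = 400)
  xd <- stats::approx(s_raw, mx, s_d)$y
  yd <- stats::approx(s_raw, my, s_d)$y
  w_at <- if (is.function(width)) {
    width(s_d / total)
  } else if (length(width) == length(mx)) {
    stats::approx(s_raw / total, width, s_d / total)$y
  } else {
    rep(width[1], length(s_d))
  }
  nx <- length(seq$x); ny <- length(seq$y)
  X <- matrix(seq$x, nx, ny)
  Y <- matrix(seq$y, nx, ny, byrow = TRUE)
  best <- matrix(Inf, nx, ny)
  wbest <- matrix(0, nx, ny)
  for (k in seq_along(s_d)) {
    d2 <- (X - xd[k])^2 + (Y - yd[k])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    wbest[upd] <- w_at[k]
  }
  wbest > 0 & sqrt(best) <= wbest / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
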