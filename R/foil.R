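#' Flapping-foil motion parameters
#'
#' Bundles the parameters of the two-degree-of-freedom (sway + yaw) foil motion
#' program together with the flow constants used for nondimensional numbers.
#' The foil is swayed laterally and yawed about a rotation center located
#' `r_te` upstream of the trailing edge, with the yaw lagging the sway by a
#' quarter period so that yaw is maximal at the sway zero crossing.
#'
#' @param a_sway Sway amplitude (m).
#' @param a_yaw Yaw amplitude (rad); must be below pi/2.
#' @param f Flapping frequency (Hz).
#' @param U Free-stream flow speed (m/s).
#' @param r_te Distance from the rotation center to the trailing edge (m).
#' @param chord Foil chord length (m).
#' @param span Foil span (m).
#' @param nu Kinematic viscosity of the fluid (m^2/s).
#'
#' @return An object of class `foil_params`.
#' @examples
#' p <- foil_params(a_sway = 0.01, a_yaw = 20 * pi / 180, f = 2, U = 0.3)
#' strouhal(0.04, p$f, p$U)
#' @export
foil_params <- function(a_sway, a_yaw, f, U,
                        r_te = 0.048, chord = 0.067, span = 0.190,
                        nu = 1e-6) {
  vals <- c(a_sway = a_sway, a_yaw = a_yaw, f = f, U = U,
            r_te = r_te, chord = chord, span = span, nu = nu)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all foil parameters must be finite and strictly positive")
  }
  if (a_yaw >= pi / 2) {
    rlang::abort("yaw amplitude `a_yaw` must be below pi/2 radians")
  }
  structure(as.list(vals), class = "foil_params")
}

#' @export
print.foil_params <- function(x, ...) {
  cat("<foil_params>\n")
  cat(sprintf("  sway %.4g m, yaw %.4g rad, f %.4g Hz, U %.4g m/s\n",
              x$a_sway, x$a_yaw, x$f, x$U))
  cat(sprintf("  chord %.4g m, span %.4g m, r_te %.4g m, nu %.3g m^2/s\n",
              x$chord, x$span, x$r_te, x$nu))
  invisible(x)
}

#' Foil pose at given times
#'
#' Evaluates the sway/yaw motion program: sway(t) = a_sway sin(2 pi f t) and
#' yaw(t) = a_yaw sin(2 pi f t - pi/2). Positive yaw deflects the trailing
#' edge toward negative y, so the quarter-period offset makes sway and yaw
#' excursions add constructively at the trailing edge.
#'
#' @param t Time or vector of times (s).
#' @param p A [foil_params()] object.
#' @return A tibble with columns `time_s`, `sway_m`, `yaw_rad`.
#' @export
foil_pose <- function(t, p) {
  stopifnot(inherits(p, "foil_params"))
  tibble::tibble(
    time_s = t,
    sway_m = p$a_sway * sin(2 * pi * p$f * t),
    yaw_rad = p$a_yaw * sin(2 * pi * p$f * t - pi / 2)
  )
}

#' Trailing-edge trajectory of the flapping foil
#'
#' Samples the lateral trailing-edge position y_te(t) = sway(t) -
#' r_te sin(yaw(t)) over at least one full flapping period. Exact
#' trigonometric kinematics are used rather than a small-angle
#' linearisation (at 20 degrees of yaw the linearisation errs by ~2%).
#'
#' @param p A [foil_params()] object.
#' @param duration Length of the sampled window (s); must cover >= 1 period.
#' @param rate Sampling rate (Hz); must be at least `100 * f` for dense
#'   coverage of the excursion extrema.
#' @return A tibble with columns `time_s`, `sway_m`, `yaw_rad`, `y_te_m`.
#' @examples
#' p <- foil_params(0.01, 20 * pi / 180, f = 2, U = 0.3)
#' path <- trailing_edge_path(p)
#' peak_to_peak(path)
#' @export
trailing_edge_path <- function(p, duration = 1 / p$f, rate = 500 * p$f) {
  stopifnot(inherits(p, "foil_params"))
  if (duration < 1 / p$f) {
    rlang::abort("`duration` must cover at least one full flapping period")
  }
  if (rate < 100 * p$f) {
    rlang::abort("`rate` must be at least 100 times the flapping frequency")
  }
  t <- seq(0, duration, by = 1 / rate)
  pose <- foil_pose(t, p)
  pose$y_te_m <- pose$sway_m - p$r_te * sin(pose$yaw_rad)
  pose
}

#' Peak-to-peak excursion of a trajectory series
#'
#' @param series A data frame with the series in `value` (default the
#'   trailing-edge column `y_te_m`), or a numeric vector.
#' @param value Column holding the series when `series` is a data frame.
#' @return max - min of the series (same units as the input).
#' @export
peak_to_peak <- function(series, value = "y_te_m") {
  x <- if (is.data.frame(series)) {
    if (!value %in% names(series)) {
      rlang::abort(sprintf("column `%s` not found in `series`", value))
    }
    series[[value]]
  } else {
    series
  }
  if (length(x) == 0 || all(!is.finite(x))) {
    rlang::abort("`series` is empty")
  }
  max(x, na.rm = TRUE) - min(x, na.rm = TRUE)
}

#' Strouhal number
#'
#' St = A f / U with A the peak-to-peak flapping (or tail-beat) amplitude.
#' Swimming fish typically operate at St between 0.2 and 0.4.
#'
#' @param A Peak-to-peak amplitude (m).
#' @param f Oscillation frequency (Hz).
#' @param U Flow or swimming speed (m/s).
#' @return Dimensionless Strouhal number.
#' @export
strouhal <- function(A, f, U) {
  if (any(U <= 0)) rlang::abort("`U` must be strictly positive")
  A * f / U
}

#' Reynolds number
#'
#' Re = U L / nu; for fish the characteristic length L is the body length,
#' for the foil its chord.
#'
#' @param U Flow speed (m/s).
#' @param L Characteristic length (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(U, L, nu) {
  if (any(nu <= 0)) rlang::abort("`nu` must be strictly positive")
  U * L / nu
}

#' Posed outline of the symmetric foil section
#'
#' Generates the closed outline of a NACA 0012 section (12% thickness, closed
#' trailing edge variant) posed by [foil_pose()]: rotated by the yaw angle
#' about the rotation center located `r_te` ahead of the trailing edge and
#' translated by the sway. Positive yaw rotates the trailing edge toward
#' negative y. x runs downstream from the leading edge at pose zero.
#'
#' @param t Time (s) defining the pose.
#' @param p A [foil_params()] object.
#' @param n Number of chordwise stations per surface; at least 20.
#' @return A tibble with columns `x_m`, `y_m`; first and last rows coincide
#'   (closed polygon).
#' @export
foil_outline <- function(t, p, n = 101) {
  stopifnot(inherits(p, "foil_params"))
  if (n < 20) rlang::abort("`n` must be at least 20 for a usable outline")
  pose <- foil_pose(t[1], p)
  # cosine-spaced chord stations, closed-trailing-edge thickness polynomial
  xc <- (1 - cos(seq(0, pi, length.out = n))) / 2
  th <- 0.12
  yt <- 5 * th * (0.2969 * sqrt(xc) - 0.1260 * xc - 0.3516 * xc^2 +
                    0.2843 * xc^3 - 0.1036 * xc^4)
  xs <- c(rev(xc), xc[-1]) * p$chord
  ys <- c(rev(yt), -yt[-1]) * p$chord
  # close the polygon exactly
  xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
  # pose about the rotation center, r_te ahead of the trailing edge
  xc0 <- p$chord - p$r_te
  ang <- -pose$yaw_rad
  dx <- xs - xc0
  tibble::tibble(
    x_m = xc0 + dx * cos(ang) - ys * sin(ang),
    y_m = pose$sway_m + dx * sin(ang) + ys * cos(ang)
  )
}
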