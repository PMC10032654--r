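#' Specification of a synthetic traveling-wave swimmer
#'
#' Parameters of a kinematic swimmer model emulating digitised ventral-video
#' midlines: lateral displacement y(s, t) = A(s) sin(2 pi f t - 2 pi s /
#' lam + phase0) along an inextensible body, with an amplitude envelope
#' A(s) = a_head + (a_tail - a_head) s^q growing toward the tail, sampled at
#' `n_markers` equal-arclength stations and `fps` frames per second, with
#' i.i.d. Gaussian tracking noise per coordinate.
#'
#' Defaults emulate the study conditions: 9 markers at 125 fps, a 0.19 m
#' trout beating at 2 Hz with a body wave of one body length and a tail
#' amplitude of 10% BL (quadratic, carangiform-like envelope).
#'
#' @param f Tail-beat frequency (Hz).
#' @param lam Body-wave wavelength in body lengths (BL).
#' @param a_head,a_tail Lateral half-amplitudes at snout and tail tip (m);
#'   `a_tail >= a_head >= 0`.
#' @param q Envelope exponent (dimensionless).
#' @param BL Body length (m).
#' @param n_markers Number of digitised midline markers (>= 2).
#' @param fps Video frame rate (Hz); must exceed `2 * f`.
#' @param noise_sd Gaussian tracking-noise s.d. per coordinate (m).
#' @param heading Heading angle (rad): rotation of the whole body about the
#'   snout; at 0 the body extends from the snout toward +x (fish facing -x).
#' @param snout_offset Snout position (m, length-2).
#' @param duration Trial duration (s).
#' @param phase0 Wave phase at the snout at t = 0 (rad).
#' @param seed Integer seed for the tracking noise; `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `swimmer_spec`.
#' @export
swimmer_spec <- function(f = 2, lam = 1.0, a_head = 0.002, a_tail = 0.019,
                         q = 2, BL = 0.19, n_markers = 9, fps = 125,
                         noise_sd = 0, heading = 0, snout_offset = c(0, 0),
                         duration = 4, phase0 = 0, seed = NULL) {
  if (a_head < 0 || a_tail < a_head) {
    rlang::abort("need a_tail >= a_head >= 0")
  }
  if (lam <= 0) rlang::abort("`lam` must be positive")
  if (n_markers < 2) rlang::abort("need at least 2 markers")
  if (fps <= 2 * f) rlang::abort("`fps` must exceed 2 * f (aliasing)")
  structure(list(f = f, lam = lam, a_head = a_head, a_tail = a_tail, q = q,
                 BL = BL, n_markers = as.integer(n_markers), fps = fps,
                 noise_sd = noise_sd, heading = heading,
                 snout_offset = snout_offset, duration = duration,
                 phase0 = phase0, seed = seed),
            class = "swimmer_spec")
}

# lateral wave and inextensible x-placement on a fine arclength grid (BL units
# for s, metres out); returns list(x, y) for one time
swimmer_curve <- function(spec, t, s_fine) {
  A <- spec$a_head + (spec$a_tail - spec$a_head) * s_fine^spec$q
  y <- A * sin(2 * pi * spec$f * t - 2 * pi * s_fine / spec$lam + spec$phase0)
  ds <- diff(s_fine) * spec$BL
  dy <- diff(y)
  if (any(abs(dy) >= ds)) {
    rlang::abort("wave slope exceeds 1; amplitude too large for an inextensible body")
  }
  x <- c(0, cumsum(sqrt(ds^2 - dy^2)))
  list(x = x, y = y)
}

#' Simulate a traveling-wave swimmer track
#'
#' Generates a [midline_track()] from a [swimmer_spec()]: markers equally
#' spaced in arclength along an inextensible body carrying the traveling
#' bending wave, rigidly rotated by the heading and translated to the snout
#' offset, with seeded Gaussian tracking noise added per coordinate.
#'
#' @param spec A [swimmer_spec()].
#' @return A [midline_track()] with `spec` attached as attribute
#'   `source_spec`.
#' @examples
#' trk <- simulate_swimmer(swimmer_spec(duration = 2, seed = 1))
#' tailbeat_frequency(trk)
#' @export
simulate_swimmer <- function(spec) {
  stopifnot(inherits(spec, "swimmer_spec"))
  n_frames <- floor(spec$duration * spec$fps) + 1L
  times <- (seq_len(n_frames) - 1L) / spec$fps
  n_fine <- max(40L * (spec$n_markers - 1L), 400L)
  s_fine <- seq(0, 1, length.out = n_fine + 1L)
  # markers sit at equal-arclength stations; s_fine is arclength by
  # construction (dx^2 + dy^2 = ds^2), so index evenly
  idx <- round(seq(1, n_fine + 1L, length.out = spec$n_markers))
  R <- matrix(c(cos(spec$heading), sin(spec$heading),
                -sin(spec$heading), cos(spec$heading)), 2, 2)
  rows <- purrr::map(seq_along(times), function(k) {
    cur <- swimmer_curve(spec, times[k], s_fine)
    xy <- cbind(cur$x[idx], cur$y[idx]) %*% t(R)
    tibble::tibble(frame = k - 1L, time_s = times[k],
                   marker = 0:(spec$n_markers - 1L),
                   x_m = xy[, 1] + spec$snout_offset[1],
                   y_m = xy[, 2] + spec$snout_offset[2])
  })
  out <- dplyr::bind_rows(rows)
  if (spec$noise_sd > 0) {
    add_noise <- function() {
      out$x_m <<- out$x_m + stats::rnorm(nrow(out), 0, spec$noise_sd)
      out$y_m <<- out$y_m + stats::rnorm(nrow(out), 0, spec$noise_sd)
    }
    if (is.null(spec$seed)) add_noise() else withr::with_seed(spec$seed, add_noise())
  }
  trk <- midline_track(out, body_length = spec$BL, fps = spec$fps)
  attr(trk, "source_spec") <- spec
  trk
}

#' Simulate wake-locked in-line followers
#'
#' Places synthetic swimmers on the wake centerline at given gap distances
#' downstream of the foil trailing edge, phase-locked to the vortex street:
#' each follower beats at the wake shedding frequency `U_c / lam_w` and its
#' wave is delayed by the vortex transit time `d / U_c`, so the foil-to-fish
#' phase difference grows linearly in distance with slope `2 pi / lam_w`.
#'
#' @param wake A [wake_spec()] providing `U_c` and `lam_w`.
#' @param swimmer A [swimmer_spec()] template (its `f`, `phase0` and
#'   `snout_offset` are overridden per follower).
#' @param distances Gap distances (m) from foil trailing edge to snout; > 0.
#' @param phase_const Additive phase constant (rad).
#' @return A tibble with columns `distance_m` and `track` (list column of
#'   [midline_track()] objects).
#' @export
simulate_inline_follower <- function(wake, swimmer, distances,
                                     phase_const = 0) {
  stopifnot(inherits(wake, "wake_spec"), inherits(swimmer, "swimmer_spec"))
  if (length(distances) == 0) rlang::abort("`distances` is empty")
  if (any(distances < 0)) rlang::abort("`distances` must be non-negative")
  f_shed <- wake$U_c / wake$lam_w
  tracks <- purrr::map(seq_along(distances), function(i) {
    d <- distances[i]
    sp <- swimmer
    sp$f <- f_shed
    sp$phase0 <- phase_const - 2 * pi * d / wake$lam_w
    sp$snout_offset <- c(d, 0)
    if (!is.null(sp$seed)) sp$seed <- sp$seed + i
    simulate_swimmer(sp)
  })
  tibble::tibble(distance_m = distances, track = tracks)
}
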