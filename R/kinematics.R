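#' Resample a midline track to equal-arclength stations
#'
#' Reproduces the standard digitisation workflow: at keyframes (every
#' `keyframe_stride`-th frame) an interpolating cubic spline is fitted
#' through the raw markers and resampled at `n_out` equal-arclength
#' stations; the frames in between are filled by linear interpolation of the
#' station coordinates between the bracketing keyframes.
#'
#' For noisy digitisations set `smooth = TRUE`: each keyframe's markers are
#' first replaced by generalised-cross-validated smoothing-spline fits along
#' arclength, the standard treatment for tracking noise. Adjacent joint
#' angles share midline stations with opposite sign, so unsmoothed white
#' marker noise is negatively correlated between neighbouring joints and
#' systematically inflates cross-correlation phase lags; smoothing removes
#' the effect at its source. With noiseless input GCV selects nearly
#' interpolating fits, so the option is safe but off by default to keep the
#' resampler strictly interpolating.
#'
#' @param raw A [midline_track()].
#' @param n_out Number of output stations; at least the raw marker count.
#' @param keyframe_stride Keyframe spacing in frames (default 6).
#' @param smooth Apply GCV smoothing splines to each keyframe first.
#' @return A [midline_track()] with `n_out` markers per frame.
#' @export
resample_midline <- function(raw, n_out = 21, keyframe_stride = 6,
                             smooth = FALSE) {
  stopifnot(inherits(raw, "midline_track"))
  n_raw <- n_markers_of(raw)
  if (n_raw < 2) rlang::abort("need at least 2 markers")
  if (n_out < n_raw) rlang::abort("`n_out` must be at least the raw marker count")
  frames <- sort(unique(raw$frame))
  keys <- frames[seq(1, length(frames), by = keyframe_stride)]
  if (keys[length(keys)] != frames[length(frames)]) {
    keys <- c(keys, frames[length(frames)])
  }
  key_stations <- lapply(keys, function(fr) {
    spline_stations(frame_coords(raw, fr), n_out, smooth = smooth)
  })
  names(key_stations) <- as.character(keys)
  times <- raw$time_s[!duplicated(raw$frame)]
  names(times) <- as.character(frames)
  rows <- purrr::map(seq_along(frames), function(i) {
    fr <- frames[i]
    ki <- findInterval(fr, keys)
    xy <- if (fr == keys[ki] || ki == length(keys)) {
      key_stations[[ki]]
    } else {
      a <- key_stations[[ki]]; b <- key_stations[[ki + 1]]
      w <- (fr - keys[ki]) / (keys[ki + 1] - keys[ki])
      (1 - w) * a + w * b
    }
    tibble::tibble(frame = fr, time_s = times[[as.character(fr)]],
                   marker = 0:(n_out - 1L), x_m = xy[, 1], y_m = xy[, 2])
  })
  out <- midline_track(dplyr::bind_rows(rows),
                       body_length = body_length(raw), fps = track_fps(raw))
  attr(out, "source_spec") <- attr(raw, "source_spec")
  out
}

# interpolating cubic spline through markers (optionally GCV-smoothed
# first), resampled at n_out equal-arclength stations
spline_stations <- function(xy, n_out, smooth = FALSE) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  if (any(seg <= 0)) rlang::abort("coincident markers in frame")
  s <- c(0, cumsum(seg))
  if (smooth && nrow(xy) >= 4) {
    xy <- cbind(stats::predict(stats::smooth.spline(s, xy[, 1]), s)$y,
                stats::predict(stats::smooth.spline(s, xy[, 2]), s)$y)
  }
  fx <- stats::splinefun(s, xy[, 1], method = "fmm")
  fy <- stats::splinefun(s, xy[, 2], method = "fmm")
  sd <- seq(0, s[length(s)], length.out = 40 * (nrow(xy) - 1) + 1)
  xd <- fx(sd); yd <- fy(sd)
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  tgt <- seq(0, arc[length(arc)], length.out = n_out)
  cbind(stats::approx(arc, xd, tgt)$y, stats::approx(arc, yd, tgt)$y)
}

# centered moving average with reflected ends: zero-phase, so peak times and
# cross-correlation lags are not biased
smooth_ma <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  n <- length(x)
  xp <- c(rev(x[seq_len(w)]), x, rev(x[(n - w + 1):n]))
  sm <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(sm[(w + 1):(w + n)])
}

# zero-phase band-pass by zeroing FFT bins outside [f_lo, f_hi]; symmetric
# gain, so cross-correlation lags are unbiased
bandpass_fft <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  fr <- (seq_len(n) - 1) * fs / n
  fr <- pmin(fr, fs - fr) # two-sided
  X[fr < f_lo | fr > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# dominant frequency of a series by the discrete-spectrum peak (excluding DC)
dominant_frequency <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:floor(n / 2)]
  fr <- seq_len(floor(n / 2) - 1) * fs / n
  fr[which.max(sp)]
}

# local maxima with prominence filter; returns indices
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    lv <- i; while (lv > 1 && x[lv - 1] <= x[i]) lv <- lv - 1L
    rv <- i; while (rv < n && x[rv + 1] <= x[i]) rv <- rv + 1L
    left_min <- min(x[max(1, lv - 1):i])
    right_min <- min(x[i:min(n, rv + 1)])
    (x[i] - max(left_min, right_min)) >= min_prominence
  }, logical(1))
  cand[keep]
}

# sub-frame quadratic refinement of a peak location
refine_peak <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(i)
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (abs(denom) < 1e-300) return(i)
  i + 0.5 * (x[i - 1] - x[i + 1]) / denom
}

#' Tail-beat frequency of a midline track
#'
#' Detects positive maxima of the heading-removed lateral tail-tip
#' displacement (prominence at least 10% of the signal half-range, peak
#' times refined to sub-frame precision by a local parabola) and averages
#' the period over the final `n_cycles` consecutive swimming cycles.
#'
#' Tracking noise is white whereas tail beats are narrowband, so the series
#' is first passed through a zero-phase moving average of about an eighth of
#' the dominant period (found from the discrete spectrum); being symmetric,
#' the filter does not shift peak times. Set `smooth = FALSE` to skip it.
#'
#' @param track A [midline_track()] spanning at least `n_cycles` full cycles.
#' @param n_cycles Number of consecutive cycles to average over (default 3).
#' @param smooth Apply the zero-phase pre-filter (default `TRUE`).
#' @return Tail-beat frequency (Hz).
#' @export
tailbeat_frequency <- function(track, n_cycles = 3, smooth = TRUE) {
  ser <- tail_tip_series(track)
  fps <- track_fps(track)
  x <- ser$lateral_m - mean(ser$lateral_m)
  if (diff(range(x)) <= 0) rlang::abort("tail tip does not oscillate")
  if (smooth) {
    f0 <- dominant_frequency(x, fps)
    if (f0 > 0) x <- smooth_ma(x, max(1, round(fps / (8 * f0))))
    x <- x - mean(x)
  }
  half_range <- diff(range(x)) / 2
  if (half_range <= 0) rlang::abort("tail tip does not oscillate")
  pk <- find_peaks(x, 0.1 * half_range)
  pk <- pk[x[pk] > 0]
  if (length(pk) < n_cycles + 1) {
    rlang::abort(sprintf(
      "insufficient cycles: found %d same-sign peaks, need %d",
      length(pk), n_cycles + 1))
  }
  pk <- utils::tail(pk, n_cycles + 1)
  tt <- vapply(pk, function(i) {
    fi <- refine_peak(x, i)
    stats::approx(seq_along(ser$time_s), ser$time_s, fi)$y
  }, numeric(1))
  1 / mean(diff(tt))
}

#' Joint angles along the body
#'
#' Divides each frame's midline into `n_segments` equal-arclength segments
#' and computes the signed angle between consecutive segment vectors,
#' yielding `n_segments - 1` joint-angle signals that carry the traveling
#' bending wave.
#'
#' @param track A resampled [midline_track()] with at least
#'   `n_segments + 1` stations.
#' @param n_segments Number of body segments N (default 20).
#' @return A tibble of class `joint_angle_series` with columns `frame`,
#'   `time_s`, `joint`, `angle_rad`, and attributes `n_segments`, `fps`.
#' @export
joint_angles <- function(track, n_segments = 20) {
  stopifnot(inherits(track, "midline_track"))
  if (n_markers_of(track) < n_segments + 1) {
    rlang::abort("track must have at least n_segments + 1 stations; resample first")
  }
  frames <- sort(unique(track$frame))
  times <- track$time_s[!duplicated(track$frame)]
  rows <- purrr::map(seq_along(frames), function(i) {
    xy <- frame_coords(track, frames[i])
    nodes <- equal_arc_nodes(xy, n_segments)
    vx <- diff(nodes[, 1]); vy <- diff(nodes[, 2])
    if (any(vx^2 + vy^2 <= 0)) rlang::abort("degenerate (zero-length) segment")
    ang <- atan2(vx[-1] * vy[-n_segments] - vy[-1] * vx[-n_segments],
                 vx[-1] * vx[-n_segments] + vy[-1] * vy[-n_segments])
    tibble::tibble(frame = frames[i], time_s = times[i],
                   joint = seq_len(n_segments - 1L), angle_rad = -ang)
  })
  structure(dplyr::bind_rows(rows),
            n_segments = as.integer(n_segments), fps = track_fps(track),
            class = c("joint_angle_series", class(tibble::tibble())))
}

# split a polyline into n equal-arclength nodes (linear interpolation along
# the already dense station chain)
equal_arc_nodes <- function(xy, n_segments) {
  arc <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
  tgt <- seq(0, arc[length(arc)], length.out = n_segments + 1)
  cbind(stats::approx(arc, xy[, 1], tgt)$y, stats::approx(arc, xy[, 2], tgt)$y)
}

# circular cross-correlation delay of b relative to a, in frames, restricted
# to [0, max_lag_frames), with parabolic sub-frame refinement; ties take the
# smallest lag (which.max)
circ_xcorr_lag <- function(a, b, max_lag_frames) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("zero-variance signal: correlation undefined")
  }
  lags <- 0:(max(1L, ceiling(max_lag_frames) - 1L))
  cc <- vapply(lags, function(l) {
    ai <- ((seq_len(n) - 1L - l) %% n) + 1L
    sum(a[ai] * b)
  }, numeric(1))
  i <- which.max(cc)
  # parabolic refinement using circular neighbours of the whole lag circle
  full <- function(l) {
    ai <- ((seq_len(n) - 1L - (l %% n)) %% n) + 1L
    sum(a[ai] * b)
  }
  l0 <- lags[i]
  cm <- full(l0 - 1); c0 <- cc[i]; cp <- full(l0 + 1)
  denom <- cm - 2 * c0 + cp
  frac <- if (abs(denom) < 1e-300) 0 else 0.5 * (cm - cp) / denom
  lag <- l0 + max(-0.5, min(0.5, frac))
  if (lag < 0) lag <- 0
  lag
}

#' Intersegmental phase lags, overall phase lag and body wavelength
#'
#' For each adjacent pair of joint-angle signals, the delay at the maximum
#' of the circular cross-correlation (over an integer number of cycles,
#' restricted to half a cycle, refined to sub-frame precision) is expressed
#' as a phase: delta_phi = 2 pi lag / T. The overall phase lag is the sum
#' along the body; the body wavelength follows as lambda = 2 pi / overall
#' (in body lengths).
#'
#' With N segments there are N - 1 joints and hence N - 2 adjacent-joint
#' lags spanning (N - 2)/N of the body. The default `method =
#' "extrapolate"` pads both body ends with the mean adjacent lag so a
#' uniform traveling wave is recovered exactly; `method = "measured"`
#' returns the plain sum of measured lags.
#'
#' @param angles A [joint_angles()] result covering at least 3 cycles.
#' @param T Cycle duration (s), e.g. `1 / tailbeat_frequency(track)`.
#' @param method `"extrapolate"` (default) or `"measured"`.
#' @param smooth Band-pass each joint-angle signal around the tail-beat
#'   frequency (zero-phase FFT filter over `[0.25/T, 1.75/T]`) before
#'   correlating (default `TRUE`). The bending wave is narrowband at the
#'   beat frequency while tracking noise is white, so the filter leaves the
#'   wave untouched over an integer number of cycles; being zero-phase it
#'   does not bias the lags, whereas unfiltered noise - partly shared
#'   between adjacent joints through common stations - scatters the
#'   correlation peak across the lag window.
#' @return An object of class `phase_lag_result`: list with `delta_phi`
#'   (rad; per-entry, extrapolated entries flagged by `measured`), `overall`
#'   (rad), `wavelength_bl`, `T`, `n_segments`, `method`.
#' @export
phase_lags <- function(angles, T, method = c("extrapolate", "measured"),
                       smooth = TRUE) {
  stopifnot(inherits(angles, "joint_angle_series"))
  method <- match.arg(method)
  fps <- attr(angles, "fps")
  n_seg <- attr(angles, "n_segments")
  wide <- tidyr::pivot_wider(angles, id_cols = c("frame", "time_s"),
                             names_from = "joint", values_from = "angle_rad")
  sig <- as.matrix(wide[, -(1:2)])
  duration <- max(wide$time_s) - min(wide$time_s)
  k_cycles <- floor(duration / T)
  if (k_cycles < 3) rlang::abort("need at least 3 full cycles of joint angles")
  n_use <- round(k_cycles * T * fps)
  n_use <- min(n_use, nrow(sig))
  sig <- sig[(nrow(sig) - n_use + 1):nrow(sig), , drop = FALSE]
  if (smooth) {
    sig <- apply(sig, 2, bandpass_fft, fs = fps,
                 f_lo = 0.25 / T, f_hi = 1.75 / T)
  }
  frames_per_cycle <- T * fps
  max_lag <- frames_per_cycle / 2
  n_joint <- ncol(sig)
  measured <- vapply(seq_len(n_joint - 1L), function(i) {
    lag <- circ_xcorr_lag(sig[, i], sig[, i + 1], max_lag)
    2 * pi * lag / frames_per_cycle
  }, numeric(1))
  if (method == "extrapolate") {
    pad <- mean(measured)
    delta <- c(pad, measured, pad)
    flag <- c(FALSE, rep(TRUE, length(measured)), FALSE)
  } else {
    delta <- measured
    flag <- rep(TRUE, length(measured))
  }
  overall <- sum(delta)
  structure(list(delta_phi = delta, measured = flag, overall = overall,
                 wavelength_bl = if (overall > 0) 2 * pi / overall else Inf,
                 T = T, n_segments = n_seg, method = method),
            class = "phase_lag_result")
}

#' @export
print.phase_lag_result <- function(x, ...) {
  cat(sprintf(
    "<phase_lag_result> overall %.3f rad (%.3f cycles), wavelength %.3f BL\n",
    x$overall, x$overall / (2 * pi), x$wavelength_bl))
  invisible(x)
}

#' Lateral amplitude envelope along the body
#'
#' Forward and lateral directions are the principal axes of the pooled cloud
#' of all tracked midline points ([body_frame()]); the amplitude at each
#' station is half the range of its lateral projection over the trial. The
#' PCA step removes the heading, so the profile is invariant under rigid
#' rotation of the track.
#'
#' @param track A [midline_track()] with at least 3 frames.
#' @return A tibble of class `amplitude_profile` with columns `s_bl`
#'   (arclength fraction of each station) and `amplitude_m`.
#' @export
amplitude_profile <- function(track) {
  stopifnot(inherits(track, "midline_track"))
  axes <- body_frame(track)
  lat <- (cbind(track$x_m - axes$center[1], track$y_m - axes$center[2]) %*%
            axes$lateral)[, 1]
  d <- dplyr::mutate(tibble::as_tibble(track), lateral_m = lat)
  arc <- dplyr::group_by(d, .data$frame)
  arc <- dplyr::mutate(arc, s_m = c(0, cumsum(sqrt(diff(.data$x_m)^2 +
                                                     diff(.data$y_m)^2))))
  arc <- dplyr::ungroup(arc)
  prof <- dplyr::group_by(arc, .data$marker)
  prof <- dplyr::summarise(
    prof,
    s_bl = mean(.data$s_m) / body_length(track),
    amplitude_m = (max(.data$lateral_m) - min(.data$lateral_m)) / 2,
    .groups = "drop")
  structure(dplyr::select(prof, "s_bl", "amplitude_m"),
            class = c("amplitude_profile", class(tibble::tibble())))
}

#' Phase difference between two trailing-edge series
#'
#' Cross-correlates the lateral trailing-edge displacement of a follower
#' (fish) against a leader (foil) over their shared time window, after
#' resampling both onto the coarser of the two time bases, and expresses the
#' delay of the follower as a phase `2 pi lag / T` in `[0, 2 pi)`.
#'
#' @param foil_te Data frame with `time_s` and a displacement column (the
#'   second column, e.g. `y_te_m` from [trailing_edge_path()]).
#' @param fish_te Data frame with `time_s` and a displacement column (e.g.
#'   `lateral_m` from [tail_tip_series()]).
#' @param T Cycle duration (s).
#' @return Phase difference (rad) in `[0, 2 pi)`.
#' @export
phase_difference <- function(foil_te, fish_te, T) {
  get_val <- function(d) {
    vcol <- setdiff(names(d), "time_s")[1]
    list(t = d$time_s, v = d[[vcol]])
  }
  a <- get_val(foil_te); b <- get_val(fish_te)
  t0 <- max(min(a$t), min(b$t))
  t1 <- min(max(a$t), max(b$t))
  if (t1 - t0 < 3 * T) rlang::abort("need at least 3 shared cycles")
  rate_a <- 1 / stats::median(diff(a$t))
  rate_b <- 1 / stats::median(diff(b$t))
  rate <- min(rate_a, rate_b)
  k_cycles <- floor((t1 - t0) / T)
  n_use <- round(k_cycles * T * rate)
  tt <- t1 - (n_use:1) / rate
  tt <- tt[tt >= t0]
  av <- stats::approx(a$t, a$v, tt)$y
  bv <- stats::approx(b$t, b$v, tt)$y
  frames_per_cycle <- T * rate
  lag <- circ_xcorr_lag(av, bv, frames_per_cycle)
  (2 * pi * lag / frames_per_cycle) %% (2 * pi)
}

#' Euclidean gap distance
#'
#' Distance between the (mean) foil trailing-edge position and the (mean)
#' fish snout position over the analysis window.
#'
#' @param foil_te_pos Length-2 vector or two-column matrix of positions (m).
#' @param fish_snout Length-2 vector or two-column matrix of positions (m).
#' @return Distance (m).
#' @export
gap_distance <- function(foil_te_pos, fish_snout) {
  p1 <- if (is.matrix(foil_te_pos)) colMeans(foil_te_pos) else foil_te_pos
  p2 <- if (is.matrix(fish_snout)) colMeans(fish_snout) else fish_snout
  sqrt(sum((p1 - p2)^2))
}

#' Phase difference versus distance for a follower set
#'
#' Computes the foil-to-fish phase difference for each wake-locked follower,
#' unwraps the phases across neighbouring distances (assuming the phase
#' grows with distance by less than a full cycle between neighbours), and
#' returns a tidy table ready for [linear_fit()].
#'
#' @param followers A tibble from [simulate_inline_follower()] (columns
#'   `distance_m`, `track`).
#' @param foil_te Leader trailing-edge series (see [phase_difference()]).
#' @param T Cycle duration (s).
#' @return A tibble with columns `distance_m`, `phase_rad` (unwrapped).
#' @export
follower_phases <- function(followers, foil_te, T) {
  ord <- order(followers$distance_m)
  d <- followers$distance_m[ord]
  ph <- vapply(followers$track[ord], function(trk) {
    phase_difference(foil_te, tail_tip_series(trk), T)
  }, numeric(1))
  for (i in seq_along(ph)[-1]) {
    while (ph[i] < ph[i - 1]) ph[i] <- ph[i] + 2 * pi
  }
  tibble::tibble(distance_m = d, phase_rad = ph)
}
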