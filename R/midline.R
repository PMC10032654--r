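#' Construct a midline track
#'
#' A midline track is a tidy table of digitised body-midline marker positions:
#' one row per frame per marker, markers ordered snout (0) to tail tip
#' (n - 1), with the body length and frame rate carried as attributes.
#'
#' @param data A data frame with columns `frame`, `time_s`, `marker`, `x_m`,
#'   `y_m`.
#' @param body_length Body length BL (m). If `NULL`, estimated as the mean
#'   polyline length of the marker chain over frames.
#' @param fps Frame rate (Hz). If `NULL`, inferred from `time_s`.
#' @return A tibble of class `midline_track`.
#' @export
midline_track <- function(data, body_length = NULL, fps = NULL) {
  req <- c("frame", "time_s", "marker", "x_m", "y_m")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("missing column: %s", missing_cols[1]))
  }
  data <- dplyr::arrange(tibble::as_tibble(data[req]), .data$frame, .data$marker)
  if (nrow(data) == 0) rlang::abort("no frames")
  counts <- dplyr::count(data, .data$frame)
  if (length(unique(counts$n)) != 1) {
    bad <- counts$frame[counts$n != counts$n[1]][1]
    rlang::abort(sprintf("non-uniform marker count at frame %d", bad))
  }
  n_mark <- counts$n[1]
  if (n_mark < 2) rlang::abort("a midline track needs at least 2 markers")
  ok <- vapply(split(data$marker, data$frame),
               function(m) identical(as.integer(m), 0:(n_mark - 1L)),
               logical(1))
  if (!all(ok)) {
    bad <- names(ok)[!ok][1]
    rlang::abort(sprintf("gap in marker indices at frame %s", bad))
  }
  times <- unique(data$time_s)
  if (any(diff(times) <= 0)) rlang::abort("times must be strictly increasing")
  if (is.null(fps)) {
    fps <- if (length(times) > 1) 1 / stats::median(diff(times)) else NA_real_
  }
  if (is.null(body_length)) {
    seg <- dplyr::group_by(data, .data$frame)
    seg <- dplyr::summarise(
      seg,
      len = sum(sqrt(diff(.data$x_m)^2 + diff(.data$y_m)^2)),
      .groups = "drop")
    body_length <- mean(seg$len)
  }
  structure(data,
            body_length_m = body_length, fps = fps,
            class = c("midline_track", class(tibble::tibble())))
}

#' Body length of a midline track
#' @param track A [midline_track()].
#' @return Body length (m).
#' @export
body_length <- function(track) attr(track, "body_length_m")

#' Frame rate of a midline track
#' @param track A [midline_track()].
#' @return Frames per second (Hz).
#' @export
track_fps <- function(track) attr(track, "fps")

n_markers_of <- function(track) length(unique(track$marker))

# matrix views: one frame -> n_markers x 2
frame_coords <- function(track, fr) {
  d <- track[track$frame == fr, ]
  cbind(d$x_m, d$y_m)
}

#' Principal body frame of a track
#'
#' Principal-component axes of the pooled cloud of all tracked midline points
#' of a trial. The first axis (most variation) is the forward direction of
#' movement, the second the lateral direction. Signs follow a fixed
#' laboratory-frame convention (each axis has a positive y-component, ties
#' broken toward positive x), so phases are comparable across trials that
#' share a tank frame; a per-trial convention tied to the wave phase would
#' inject half-cycle offsets between trials.
#'
#' @param track A [midline_track()].
#' @return A list with `center` (length-2), `forward` and `lateral` unit
#'   vectors.
#' @export
body_frame <- function(track) {
  pts <- cbind(track$x_m, track$y_m)
  if (length(unique(track$frame)) < 3) {
    rlang::abort("need at least 3 frames to estimate the body frame")
  }
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  orient <- function(v) {
    if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) -v else v
  }
  list(center = pc$center,
       forward = orient(pc$rotation[, 1]),
       lateral = orient(pc$rotation[, 2]))
}

#' Lateral tail-tip displacement series
#'
#' Projects the tail-tip marker on the lateral axis of the principal body
#' frame (heading removed).
#'
#' @param track A [midline_track()].
#' @param frame_axes Optional precomputed [body_frame()].
#' @return A tibble with columns `time_s`, `lateral_m`.
#' @export
tail_tip_series <- function(track, frame_axes = NULL) {
  if (is.null(frame_axes)) frame_axes <- body_frame(track)
  tail_id <- max(track$marker)
  tail <- track[track$marker == tail_id, ]
  rel <- cbind(tail$x_m - frame_axes$center[1], tail$y_m - frame_axes$center[2])
  tibble::tibble(time_s = tail$time_s,
                 lateral_m = as.numeric(rel %*% frame_axes$lateral))
}
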