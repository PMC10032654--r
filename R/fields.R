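#' Planar velocity-field sequence
#'
#' Container for a sequence of planar velocity fields on a shared regular
#' grid, as produced by particle image velocimetry or by the synthetic wake
#' generators: `u` and `v` are `nx x ny x n_frames` arrays (x along the first
#' dimension), `mask` an optional solid mask (`TRUE` = solid), either static
#' (`nx x ny`) or per frame.
#'
#' @param x,y Grid node coordinates (m), strictly increasing, uniform step.
#' @param u,v Velocity component arrays, dim `c(length(x), length(y), nt)`.
#' @param dt Frame interval (s).
#' @param U_inf Free-stream speed (m/s).
#' @param rho Fluid density (kg/m^3).
#' @param mask Optional logical solid mask, `nx x ny` or `nx x ny x nt`.
#' @return An object of class `vf_seq`.
#' @export
vf_seq <- function(x, y, u, v, dt, U_inf = NA_real_, rho = 1000, mask = NULL) {
  nx <- length(x); ny <- length(y)
  if (length(dim(u)) == 2) u <- array(u, c(nx, ny, 1))
  if (length(dim(v)) == 2) v <- array(v, c(nx, ny, 1))
  stopifnot(all(dim(u) == dim(v)), dim(u)[1] == nx, dim(u)[2] == ny)
  if (dt <= 0) rlang::abort("`dt` must be positive")
  if (nx > 1 && max(abs(diff(diff(x)))) > 1e-9 * abs(diff(range(x)))) {
    rlang::abort("`x` grid must be uniform")
  }
  if (ny > 1 && max(abs(diff(diff(y)))) > 1e-9 * abs(diff(range(y)))) {
    rlang::abort("`y` grid must be uniform")
  }
  if (!is.null(mask)) {
    if (length(dim(mask)) == 2) stopifnot(all(dim(mask) == c(nx, ny)))
    else stopifnot(all(dim(mask) == dim(u)))
  }
  structure(list(x = x, y = y, u = u, v = v, dt = dt,
                 U_inf = U_inf, rho = rho, mask = mask),
            class = "vf_seq")
}

#' @export
print.vf_seq <- function(x, ...) {
  cat(sprintf("<vf_seq> %d x %d grid, %d frame(s), dt = %.4g s\n",
              length(x$x), length(x$y), dim(x$u)[3], x$dt))
  invisible(x)
}

n_frames_of <- function(seq) dim(seq$u)[3]

grid_step <- function(seq) {
  if (length(seq$x) > 1) diff(seq$x)[1] else diff(seq$y)[1]
}

#' Solid mask of one frame
#' @param seq A [vf_seq()].
#' @param frame Frame index (1-based).
#' @return Logical `nx x ny` matrix, `TRUE` on solid nodes.
#' @export
mask_at <- function(seq, frame = 1) {
  if (is.null(seq$mask)) {
    return(matrix(FALSE, length(seq$x), length(seq$y)))
  }
  if (length(dim(seq$mask)) == 2) seq$mask else seq$mask[, , frame]
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.vf_seq <- function(x, ...) {
  nx <- length(x$x); ny <- length(x$y); nt <- n_frames_of(x)
  grid <- expand.grid(x_m = x$x, y_m = x$y, KEEP.OUT.ATTRS = FALSE)
  purrr::map_dfr(seq_len(nt), function(fr) {
    tibble::tibble(frame = fr - 1L, time_s = (fr - 1L) * x$dt,
                   x_m = grid$x_m, y_m = grid$y_m,
                   u_mps = as.vector(x$u[, , fr]),
                   v_mps = as.vector(x$v[, , fr]),
                   solid = as.vector(mask_at(x, fr)))
  })
}

#' Subtract the mean flow from a velocity sequence
#'
#' Removes the spatial-temporal mean of the streamwise component over fluid
#' nodes, the standard step for visualising vortex streets: a uniform
#' subtraction leaves the curl untouched, so vortices appear as closed
#' circulation patterns. The subtracted value is recorded as attribute
#' `subtracted_u_mps`.
#'
#' @param seq A [vf_seq()].
#' @return A [vf_seq()] with zero-mean `u` on fluid nodes.
#' @export
subtract_mean_flow <- function(seq) {
  stopifnot(inherits(seq, "vf_seq"))
  nt <- n_frames_of(seq)
  fluid <- array(TRUE, dim(seq$u))
  for (fr in seq_len(nt)) fluid[, , fr] <- !mask_at(seq, fr)
  ubar <- mean(seq$u[fluid])
  out <- seq
  out$u <- seq$u - ubar
  attr(out, "subtracted_u_mps") <- ubar
  out
}

# central-difference spatial derivative along dim 1 (x) or 2 (y), one-sided at
# boundaries and next to invalid (masked / NA) nodes; NA where no valid
# neighbour exists
deriv_mat <- function(M, h, along, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(M)
  M[!valid] <- NA_real_
  shift <- function(A, k) {
    # shift along `along` by k, padding NA
    n <- dim(A)[along]
    idx <- seq_len(n) + k
    pad <- idx < 1 | idx > n
    idx[pad] <- 1
    out <- if (along == 1) A[idx, , drop = FALSE] else A[, idx, drop = FALSE]
    if (along == 1) out[pad, ] <- NA_real_ else out[, pad] <- NA_real_
    out
  }
  Mp <- shift(M, 1); Mm <- shift(M, -1)
  ok_p <- is.finite(Mp); ok_m <- is.finite(Mm)
  d <- matrix(NA_real_, nrow(M), ncol(M))
  both <- ok_p & ok_m & valid
  d[both] <- (Mp[both] - Mm[both]) / (2 * h)
  fwd <- ok_p & !ok_m & valid
  d[fwd] <- (Mp[fwd] - M[fwd]) / h
  bwd <- !ok_p & ok_m & valid
  d[bwd] <- (M[bwd] - Mm[bwd]) / h
  d
}

#' Out-of-plane vorticity of one frame
#'
#' omega_z = dv/dx - du/dy by central differences (one-sided at boundaries
#' and solid masks).
#'
#' @param seq A [vf_seq()].
#' @param frame Frame index (1-based).
#' @return An `nx x ny` matrix (1/s), `NA` on solid nodes.
#' @export
vorticity <- function(seq, frame = 1) {
  h <- grid_step(seq)
  valid <- !mask_at(seq, frame)
  dvdx <- deriv_mat(seq$v[, , frame], h, 1, valid)
  dudy <- deriv_mat(seq$u[, , frame], h, 2, valid)
  dvdx - dudy
}

# connected components of a logical matrix (4-connectivity), simple stack
# flood fill; grids here are small
label_blobs <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          a <- p[1] + d[1]; b <- p[2] + d[2]
          if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
              mask[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- cur
            stack[[length(stack) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  lab
}

#' Detect vortex centers in one frame
#'
#' Thresholds the out-of-plane vorticity magnitude at a fraction of the frame
#' maximum, labels connected blobs, and reports each blob's
#' vorticity-magnitude-weighted centroid at sub-cell precision together with
#' its rotation sign.
#'
#' @param seq A [vf_seq()].
#' @param frame Frame index (1-based).
#' @param threshold_frac Threshold as a fraction of max |vorticity|.
#' @return A tibble with columns `x_m`, `y_m`, `sign`, `peak_vorticity`,
#'   ordered downstream (by `x_m`); empty for vorticity-free frames.
#' @export
vortex_centers <- function(seq, frame = 1, threshold_frac = 0.25) {
  om <- vorticity(seq, frame)
  om[!is.finite(om)] <- 0
  peak <- max(abs(om))
  if (peak <= 1e-12) {
    return(tibble::tibble(x_m = numeric(), y_m = numeric(),
                          sign = numeric(), peak_vorticity = numeric()))
  }
  out <- purrr::map_dfr(c(1, -1), function(sgn) {
    m <- (sgn * om) > threshold_frac * peak
    if (!any(m)) return(NULL)
    lab <- label_blobs(m)
    purrr::map_dfr(seq_len(max(lab)), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      w <- abs(om[lab == k])
      tibble::tibble(
        x_m = sum(seq$x[idx[, 1]] * w) / sum(w),
        y_m = sum(seq$y[idx[, 2]] * w) / sum(w),
        sign = sgn,
        peak_vorticity = max(sgn * om[lab == k]) * sgn)
    })
  })
  dplyr::arrange(out, .data$x_m)
}
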