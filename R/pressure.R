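#' Pressure-reconstruction configuration
#'
#' @param rho Fluid density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s); used only when `include_viscous`.
#' @param time_scheme Finite-difference scheme for du/dt: `"forward"` (frames
#'   f, f+1) or `"central"` (frames f-1, f+1).
#' @param include_viscous Add the viscous term mu Laplacian(u)? Off by
#'   default: at the Reynolds numbers of fish and foil wakes (2e4-5e4) the
#'   viscous contribution to the pressure gradient is negligible.
#' @return An object of class `pressure_config`.
#' @export
pressure_config <- function(rho = 1000, mu = 0,
                            time_scheme = c("forward", "central"),
                            include_viscous = FALSE) {
  time_scheme <- match.arg(time_scheme)
  if (rho <= 0) rlang::abort("`rho` must be positive")
  if (mu < 0) rlang::abort("`mu` must be non-negative")
  structure(list(rho = rho, mu = mu, time_scheme = time_scheme,
                 include_viscous = include_viscous),
            class = "pressure_config")
}

#' Pressure-gradient field from sequential velocity fields
#'
#' Estimates the planar pressure gradient from the Eulerian momentum
#' balance: grad p = -rho (du/dt + (u . grad) u) + mu Laplacian(u),
#' componentwise on fluid nodes. The time derivative uses the configured
#' scheme over the frame interval; spatial derivatives are central with
#' one-sided stencils at domain boundaries and next to solid-mask nodes;
#' solid nodes are excluded (NA).
#'
#' @param seq A [vf_seq()] with at least 2 frames.
#' @param frame Frame index (1-based); needs `frame + 1` (forward) or both
#'   neighbours (central) to exist.
#' @param cfg A [pressure_config()].
#' @return A list of class `pressure_gradient` with matrices `dpdx`, `dpdy`
#'   (Pa/m), the grid vectors `x`, `y`, the `mask` used, and `h`.
#' @export
pressure_gradient <- function(seq, frame = 1, cfg = pressure_config()) {
  stopifnot(inherits(seq, "vf_seq"), inherits(cfg, "pressure_config"))
  nt <- n_frames_of(seq)
  if (nt < 2) rlang::abort("need at least two sequential velocity frames")
  if (cfg$time_scheme == "forward" && frame + 1 > nt) {
    rlang::abort("forward scheme needs frame + 1")
  }
  if (cfg$time_scheme == "central" && (frame - 1 < 1 || frame + 1 > nt)) {
    rlang::abort("central scheme needs both neighbouring frames")
  }
  h <- grid_step(seq)
  solid <- mask_at(seq, frame)
  valid <- !solid
  u0 <- seq$u[, , frame]; v0 <- seq$v[, , frame]
  if (cfg$time_scheme == "forward") {
    dudt <- (seq$u[, , frame + 1] - u0) / seq$dt
    dvdt <- (seq$v[, , frame + 1] - v0) / seq$dt
  } else {
    dudt <- (seq$u[, , frame + 1] - seq$u[, , frame - 1]) / (2 * seq$dt)
    dvdt <- (seq$v[, , frame + 1] - seq$v[, , frame - 1]) / (2 * seq$dt)
  }
  dudx <- deriv_mat(u0, h, 1, valid); dudy <- deriv_mat(u0, h, 2, valid)
  dvdx <- deriv_mat(v0, h, 1, valid); dvdy <- deriv_mat(v0, h, 2, valid)
  ax <- dudt + u0 * dudx + v0 * dudy
  ay <- dvdt + u0 * dvdx + v0 * dvdy
  dpdx <- -cfg$rho * ax
  dpdy <- -cfg$rho * ay
  if (cfg$include_viscous && cfg$mu > 0) {
    dpdx <- dpdx + cfg$mu * laplacian_mat(u0, h, valid)
    dpdy <- dpdy + cfg$mu * laplacian_mat(v0, h, valid)
  }
  dpdx[solid] <- NA_real_
  dpdy[solid] <- NA_real_
  structure(list(dpdx = dpdx, dpdy = dpdy, x = seq$x, y = seq$y,
                 mask = solid, h = h),
            class = "pressure_gradient")
}

laplacian_mat <- function(M, h, valid) {
  d2 <- function(along) {
    g <- deriv_mat(M, h, along, valid)
    deriv_mat(g, h, along, valid & is.finite(g))
  }
  d2(1) + d2(2)
}

# march a line of nodes in one direction: trapezoidal accumulation of the
# along-path gradient g (already projected on the step), starting from s0;
# solid nodes block the path from there on (NA)
march_line <- function(g, solid, dl, s0) {
  n <- length(g)
  out <- rep(NA_real_, n)
  if (is.na(s0)) return(out)
  gg <- g
  gg[!is.finite(gg)] <- 0
  inc <- c(0, 0.5 * (gg[-n] + gg[-1]) * dl)
  val <- s0 + cumsum(inc)
  blocked <- cumsum(solid | !is.finite(g)) > 0
  val[blocked] <- NA_real_
  val
}

# one family: globally consistent sweep in direction (di, dj). The seed edge
# adjacent to the anchor corner is integrated first (from the anchor, at
# p = 0), then every line marches across the domain in (di, dj).
family_field <- function(dpdx, dpdy, solid, h, di, dj) {
  nx <- nrow(dpdx); ny <- ncol(dpdx)
  p <- matrix(NA_real_, nx, ny)
  i0 <- if (di >= 0) 1L else nx
  j0 <- if (dj >= 0) 1L else ny
  jdir <- if (dj >= 0) 1L else -1L
  idir <- if (di >= 0) 1L else -1L
  if (di != 0 && dj == 0) {
    # axis sweep in x: seed the starting column edge i = i0 along y from j0
    seed <- march_line(dpdy[i0, seq(j0, ny - j0 + 1L, by = jdir)],
                       solid[i0, seq(j0, ny - j0 + 1L, by = jdir)], h * jdir, 0)
    jseq <- seq(j0, ny - j0 + 1L, by = jdir)
    for (k in seq_along(jseq)) {
      j <- jseq[k]
      iseq <- seq(i0, nx - i0 + 1L, by = idir)
      p[iseq, j] <- march_line(dpdx[iseq, j], solid[iseq, j], h * idir, seed[k])
    }
  } else if (di == 0 && dj != 0) {
    seed <- march_line(dpdx[seq(i0, nx - i0 + 1L, by = idir), j0],
                       solid[seq(i0, nx - i0 + 1L, by = idir), j0], h * idir, 0)
    iseq <- seq(i0, nx - i0 + 1L, by = idir)
    for (k in seq_along(iseq)) {
      i <- iseq[k]
      jseq <- seq(j0, ny - j0 + 1L, by = jdir)
      p[i, jseq] <- march_line(dpdy[i, jseq], solid[i, jseq], h * jdir, seed[k])
    }
  } else {
    # diagonal sweep: seed both edges adjacent to the anchor corner, then
    # march every diagonal; step projects both gradient components
    iseq_all <- seq(i0, nx - i0 + 1L, by = idir)
    jseq_all <- seq(j0, ny - j0 + 1L, by = jdir)
    seed_i <- march_line(dpdx[iseq_all, j0], solid[iseq_all, j0], h * idir, 0)
    seed_j <- march_line(dpdy[i0, jseq_all], solid[i0, jseq_all], h * jdir, 0)
    starts <- rbind(
      cbind(i = iseq_all, j = j0, s0 = seed_i),
      cbind(i = i0, j = jseq_all[-1], s0 = seed_j[-1]))
    for (r in seq_len(nrow(starts))) {
      i <- starts[r, "i"]; j <- starts[r, "j"]; s0 <- starts[r, "s0"]
      ii <- seq(i, if (di > 0) nx else 1L, by = idir)
      jj <- seq(j, if (dj > 0) ny else 1L, by = jdir)
      m <- min(length(ii), length(jj))
      ii <- ii[seq_len(m)]; jj <- jj[seq_len(m)]
      lin <- cbind(ii, jj)
      g <- dpdx[lin] * idir + dpdy[lin] * jdir # per unit h along each axis
      p[lin] <- march_line(g, solid[lin], h, s0)
    }
  }
  p
}

#' Integrate a pressure-gradient field into a pressure field
#'
#' Reconstructs the pressure by polling eight families of straight
#' integration paths aligned with the principal grid directions (E, W, N, S
#' and the four diagonals). Each family is one globally consistent sweep,
#' seeded along a domain edge from an anchor corner at p = 0, so that for a
#' conservative gradient every family reproduces node-to-node pressure
#' differences exactly; the node pressure is the median (or mean) across
#' families. Paths hitting a solid-mask node are discarded beyond it for
#' that family; nodes left with no surviving family are filled from the
#' nearest defined fluid node (Euclidean distance, ties by row-major order).
#' The field is finally gauged to zero mean over the defined domain-boundary
#' nodes, the reference the method assumes where paths are initiated.
#'
#' @param grad A [pressure_gradient()] result (or compatible list with
#'   `dpdx`, `dpdy`, `x`, `y`, `h`).
#' @param mask Optional logical solid mask overriding `grad$mask`.
#' @param stat Aggregation across the eight families: `"median"` (robust,
#'   default) or `"mean"`.
#' @return An object of class `pressure_field`: list with grid vectors `x`,
#'   `y`, matrix `p` (Pa, `NA` on solid nodes), logical matrix `defined`
#'   (`TRUE` where at least one path family survived; enclosed nodes carry a
#'   filled value but stay flagged undefined).
#' @export
integrate_pressure <- function(grad, mask = NULL, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  solid <- mask %||% grad$mask %||%
    matrix(FALSE, nrow(grad$dpdx), ncol(grad$dpdx))
  if (all(solid)) rlang::abort("all nodes are masked solid")
  h <- grad$h
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nx <- nrow(grad$dpdx); ny <- ncol(grad$dpdx)
  cands <- array(NA_real_, c(nx, ny, 8))
  for (k in seq_along(dirs)) {
    cands[, , k] <- family_field(grad$dpdx, grad$dpdy, solid, h,
                                 dirs[[k]][1], dirs[[k]][2])
  }
  agg <- if (stat == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  p <- apply(cands, c(1, 2), agg)
  p[solid] <- NA_real_
  # nodes with at least one surviving family count as defined; enclosed
  # nodes get a filled value below but stay flagged undefined
  defined <- !solid & is.finite(p)
  had_candidate <- defined
  # fill enclosed fluid nodes from the nearest defined neighbour
  undef <- which(!solid & !is.finite(p), arr.ind = TRUE)
  if (nrow(undef) > 0) {
    def_idx <- which(defined, arr.ind = TRUE)
    for (r in seq_len(nrow(undef))) {
      d2 <- (def_idx[, 1] - undef[r, 1])^2 + (def_idx[, 2] - undef[r, 2])^2
      best <- which(d2 == min(d2))
      # row-major tie-break: smallest (j - 1) * nx + i
      lin <- (def_idx[best, 2] - 1) * nx + def_idx[best, 1]
      pick <- best[which.min(lin)]
      p[undef[r, 1], undef[r, 2]] <- p[def_idx[pick, 1], def_idx[pick, 2]]
    }
  }
  # gauge: zero mean over defined boundary nodes
  bnd <- matrix(FALSE, nx, ny)
  bnd[1, ] <- TRUE; bnd[nx, ] <- TRUE; bnd[, 1] <- TRUE; bnd[, ny] <- TRUE
  ref <- bnd & !solid & is.finite(p)
  if (any(ref)) p <- p - mean(p[ref])
  structure(list(x = grad$x, y = grad$y, p = p, defined = had_candidate),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %d x %d grid, p in [%.3g, %.3g] Pa\n",
              length(x$x), length(x$y),
              min(x$p, na.rm = TRUE), max(x$p, na.rm = TRUE)))
  invisible(x)
}

#' @export
as_tibble.pressure_field <- function(x, ...) {
  grid <- expand.grid(x_m = x$x, y_m = x$y, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(x_m = grid$x_m, y_m = grid$y_m,
                 p_pa = as.vector(x$p), defined = as.vector(x$defined))
}

#' Mean head pressure in the snout box
#'
#' Averages the pressure over a rectangular zone extending 0.1 body lengths
#' backward from the snout (opposite the heading, i.e. toward the tail) and
#' spanning the body width laterally, excluding solid and undefined nodes.
#' This is the quantity whose reduction in a thrust wake indicates reduced
#' pressure drag (F = p S with S the frontal area).
#'
#' @param p A [pressure_field()].
#' @param snout Snout position (m, length-2).
#' @param heading Facing direction of the fish (rad; 0 faces +x).
#' @param BL Body length (m).
#' @param width Body width (m).
#' @param S Optional frontal area (m^2); when given, the drag force
#'   `F = p_mean * S` is attached as attribute `force_n`.
#' @return Mean head pressure (Pa).
#' @export
head_pressure <- function(p, snout, heading, BL, width, S = NULL) {
  stopifnot(inherits(p, "pressure_field"))
  ax <- -c(cos(heading), sin(heading)) # backward (toward tail)
  nv <- c(-ax[2], ax[1])
  grid <- expand.grid(x = p$x, y = p$y, KEEP.OUT.ATTRS = FALSE)
  rx <- grid$x - snout[1]; ry <- grid$y - snout[2]
  axial <- rx * ax[1] + ry * ax[2]
  lateral <- rx * nv[1] + ry * nv[2]
  inside <- axial >= 0 & axial <= 0.1 * BL & abs(lateral) <= width / 2
  sel <- inside & as.vector(p$defined)
  if (!any(inside)) rlang::abort("snout box lies outside the grid")
  if (!any(sel)) rlang::abort("snout box contains no defined fluid nodes")
  pm <- mean(as.vector(p$p)[sel])
  if (!is.null(S)) attr(pm, "force_n") <- pm * S
  pm
}

#' Head-pressure time series over a velocity sequence
#'
#' Convenience wrapper: reconstructs the pressure field frame by frame and
#' evaluates [head_pressure()] in each, holding body mask and snout pose
#' fixed.
#'
#' @param seq A [vf_seq()].
#' @param cfg A [pressure_config()].
#' @param mask Logical solid mask (static).
#' @param snout,heading,BL,width As in [head_pressure()].
#' @param frames Frame indices to evaluate (default: all usable frames).
#' @return A tibble with columns `time_s`, `p_head_pa`.
#' @export
head_pressure_series <- function(seq, cfg, mask, snout, heading, BL, width,
                                 frames = NULL) {
  nt <- n_frames_of(seq)
  usable <- if (cfg$time_scheme == "forward") seq_len(nt - 1) else 2:(nt - 1)
  frames <- frames %||% usable
  seq$mask <- mask
  purrr::map_dfr(frames, function(fr) {
    g <- pressure_gradient(seq, fr, cfg)
    pf <- integrate_pressure(g)
    tibble::tibble(time_s = (fr - 1) * seq$dt,
                   p_head_pa = head_pressure(pf, snout, heading, BL, width))
  })
}
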