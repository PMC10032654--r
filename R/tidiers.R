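#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.welch_t <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$t, df = x$df,
                 p.value = x$p, alternative = x$alternative,
                 method = if (x$paired) "paired t-test" else "Welch t-test")
}

#' @export
glance.welch_t <- function(x, ...) tidy(x)

#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = x$n)
}

#' @export
tidy.phase_lag_result <- function(x, ...) {
  tibble::tibble(entry = seq_along(x$delta_phi),
                 delta_phi_rad = x$delta_phi,
                 measured = x$measured)
}

#' @export
glance.phase_lag_result <- function(x, ...) {
  tibble::tibble(overall_rad = x$overall,
                 wavelength_bl = x$wavelength_bl,
                 cycle_s = x$T, n_segments = x$n_segments,
                 method = x$method)
}
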