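#' Welch t-test between two condition samples
#'
#' Unequal-variance (Welch) t-test with Satterthwaite degrees of freedom,
#' the study-design default for comparing kinematic summaries between the
#' free-stream and thrust-wake conditions. The direction of a one-sided test
#' is always an explicit argument, never inferred from the data. When the
#' samples are paired by individual, a classical paired t-test is available
#' via `paired = TRUE`.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param alternative `"two_sided"`, `"less"` (mean of `a` less than mean of
#'   `b`) or `"greater"`.
#' @param paired Use the classical paired t-test instead of Welch.
#' @return An object of class `welch_t` with fields `t`, `df`, `p`,
#'   `alternative`, `paired`, `estimate` (mean difference a - b).
#' @export
welch_t <- function(a, b, alternative = c("two_sided", "less", "greater"),
                    paired = FALSE) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort("each sample needs at least 2 observations")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    rlang::abort("both samples have zero variance")
  }
  ht <- stats::t.test(a, b,
                      alternative = sub("_", ".", alternative),
                      var.equal = FALSE, paired = paired)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, alternative = alternative, paired = paired,
                 estimate = mean(a) - mean(b),
                 n = c(length(a), length(b))),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("<welch_t%s> t = %.4g, df = %.4g, p = %.4g (%s)\n",
              if (x$paired) " paired" else "", x$t, x$df, x$p, x$alternative))
  invisible(x)
}

#' Ordinary least-squares line with R-squared
#'
#' Fits y = intercept + slope x and reports the coefficient of
#' determination, as used for the phase-difference-versus-distance
#' relationship.
#'
#' @param data A data frame, or the x vector when `y` is given as a vector.
#' @param x,y Column names (unquoted) when `data` is a data frame; otherwise
#'   `data` and `x` are taken as the x and y vectors.
#' @return An object of class `linear_fit` with fields `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit as `model`.
#' @examples
#' linear_fit(tibble::tibble(d = 1:5, ph = 2 * (1:5) + 1), d, ph)
#' @export
linear_fit <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- dplyr::pull(data, {{ x }})
    yv <- dplyr::pull(data, {{ y }})
  } else {
    xv <- data
    yv <- x
  }
  if (length(xv) < 3) rlang::abort("need at least 3 points")
  if (stats::sd(xv) == 0) rlang::abort("`x` is constant; slope undefined")
  fit <- stats::lm(yv ~ xv)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n = length(xv), model = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Condition comparison report
#'
#' Summarises per-individual kinematic metrics across two experimental
#' conditions (e.g. free-stream versus thrust-wake swimming): per-group mean
#' and s.d. per condition, percent change relative to the reference
#' condition, and attached Welch tests (plus classical paired tests, since
#' individuals are paired across conditions). Individuals missing either
#' condition are excluded with a warning.
#'
#' @param trials A data frame with columns `individual`, `condition`, an
#'   optional `group`, and one column per metric. Multiple trials per
#'   individual and condition are averaged first.
#' @param metrics Character vector of metric column names.
#' @param reference Condition level used as the reference (percent change is
#'   `100 (ref - other) / ref`, so a decrease is positive).
#' @param alternative Named character vector mapping metrics to the Welch
#'   alternative (`reference` sample first); defaults to `"two_sided"` for
#'   unlisted metrics.
#' @return A tibble with one row per group and metric: means, s.d.s,
#'   `percent_change`, `t`, `df`, `p_welch`, `p_paired`, `n`.
#' @export
condition_report <- function(trials, metrics,
                             reference = "free_stream",
                             alternative = c(frequency_hz = "greater",
                                             delta_phi_rad = "greater")) {
  stopifnot(all(metrics %in% names(trials)))
  if (!"group" %in% names(trials)) trials$group <- "all"
  conds <- unique(trials$condition)
  if (!reference %in% conds || length(conds) != 2) {
    rlang::abort("`trials` must contain exactly two conditions incl. the reference")
  }
  other <- setdiff(conds, reference)
  per_ind <- dplyr::summarise(
    dplyr::group_by(trials, .data$group, .data$individual, .data$condition),
    dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop")
  have <- dplyr::count(per_ind, .data$group, .data$individual)
  unpaired <- have[have$n != 2, ]
  if (nrow(unpaired) > 0) {
    rlang::warn(sprintf("excluding %d unpaired individual(s): %s",
                        nrow(unpaired),
                        paste(unpaired$individual, collapse = ", ")))
    per_ind <- dplyr::anti_join(per_ind, unpaired[, c("group", "individual")],
                                by = c("group", "individual"))
  }
  purrr::map_dfr(unique(per_ind$group), function(g) {
    dg <- per_ind[per_ind$group == g, ]
    purrr::map_dfr(metrics, function(m) {
      wide <- tidyr::pivot_wider(dg[, c("individual", "condition", m)],
                                 names_from = "condition",
                                 values_from = dplyr::all_of(m))
      aa <- wide[[reference]]; bb <- wide[[other]]
      alt <- unname(alternative[m])
      if (is.na(alt) || is.null(alt)) alt <- "two_sided"
      w <- welch_t(aa, bb, alternative = alt)
      pp <- welch_t(aa, bb, alternative = alt, paired = TRUE)
      tibble::tibble(
        group = g, metric = m,
        mean_ref = mean(aa), sd_ref = stats::sd(aa),
        mean_other = mean(bb), sd_other = stats::sd(bb),
        percent_change = 100 * (mean(aa) - mean(bb)) / mean(aa),
        t = w$t, df = w$df, p_welch = w$p, p_paired = pp$p,
        n = length(aa))
    })
  })
}
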