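#' Validate a headspace gas measurement series
#'
#' One row per injection: `treatment`, `day`, `replicate`, `butane_amount`
#' (any consistent unit). Day 0 must be present for every treatment so
#' residual fractions are defined.
#'
#' @param df data.frame of measurements.
#' @return the validated data.frame (class `gas_series`).
#' @export
gas_series <- function(df) {
  need <- c("treatment", "day", "replicate", "butane_amount")
  if (!all(need %in% names(df)))
    stop("gas series needs columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$butane_amount)) || any(df$butane_amount < 0))
    stop("butane amounts must be finite and non-negative")
  for (trt in unique(df$treatment)) {
    if (!any(df$day[df$treatment == trt] == 0))
      stop("day 0 measurements missing for treatment ", trt)
  }
  class(df) <- c("gas_series", "data.frame")
  df
}

#' Residual gas fraction at a given day
#'
#' Mean measured amount at `day` divided by the mean at day 0 for the same
#' treatment; R(0) = 1 by construction and the value is unit-free.
#'
#' @param series a [gas_series()].
#' @param treatment treatment label.
#' @param day measurement day.
#' @return residual fraction (scalar).
#' @export
residual_fraction <- function(series, treatment, day) {
  sel0 <- series$treatment == treatment & series$day == 0
  selt <- series$treatment == treatment & series$day == day
  if (!any(selt)) stop("no measurements for treatment ", treatment, " at day ", day)
  m0 <- mean(series$butane_amount[sel0])
  if (m0 <= 0) stop("day-0 mean amount is zero for treatment ", treatment)
  mean(series$butane_amount[selt]) / m0
}

#' Biodegradation as residual-difference percentage points
#'
#' Biodegradation is the total reduction minus the physical loss, expressed
#' on residual fractions so live and sterile bottles need not share initial
#' loadings: `B = 100 * (R_sterile - R_live)`. A noise-induced negative
#' difference is clamped to 0 for reporting; the raw value is kept in the
#' `raw` attribute and a `clamped` attribute flags the case.
#'
#' @param r_live residual fraction of the live microcosm.
#' @param r_sterile residual fraction of the sterile control.
#' @return biodegradation in percentage points, with attributes `raw` and
#'   `clamped`.
#' @export
biodegradation_percent <- function(r_live, r_sterile) {
  if (any(c(r_live, r_sterile) < 0) || any(c(r_live, r_sterile) > 1.2))
    stop("residual fractions must lie in [0, 1.2]")
  raw <- 100 * (r_sterile - r_live)
  out <- max(raw, 0)
  if (raw < 0) warning("negative biodegradation estimate clamped to 0")
  structure(out, raw = raw, clamped = raw < 0)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classical equal-variance two-tailed test: pooled standard deviation,
#' `df = n_x + n_y - 2`. Degenerate zero-variance samples are resolved by
#' convention: equal means give p = 1, different means p = 0 with a
#' `degenerate` flag.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list `t`, `df`, `p`, `degenerate`.
#' @export
students_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample must contain at least 2 observations")
  df <- length(x) + length(y) - 2
  pooled_var <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) / df
  if (pooled_var == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

#' Per-day biodegradation table with significance tests
#'
#' For each post-zero day: residual fractions of the live and sterile
#' treatments, the biodegradation estimate, and a pooled-variance Student's
#' t-test comparing per-replicate residual fractions (each measurement row
#' is one observation, normalized by its treatment's day-0 mean).
#'
#' @param series a [gas_series()].
#' @param live live treatment label (default `"12C-BT"`).
#' @param sterile sterile control label (default `"12C-ST"`).
#' @param alpha significance level.
#' @return data.frame: `day`, `R_live`, `R_sterile`, `biodegradation_pct`,
#'   `raw_difference`, `t_stat`, `df`, `p_value`, `significant`.
#' @export
degradation_table <- function(series, live = "12C-BT", sterile = "12C-ST",
                              alpha = 0.05) {
  days <- sort(unique(series$day[series$treatment == live]))
  days <- days[days > 0]
  m0_live <- mean(series$butane_amount[series$treatment == live & series$day == 0])
  m0_st <- mean(series$butane_amount[series$treatment == sterile & series$day == 0])
  rows <- lapply(days, function(d) {
    rl <- residual_fraction(series, live, d)
    rs <- residual_fraction(series, sterile, d)
    b <- biodegradation_percent(rl, rs)
    x <- series$butane_amount[series$treatment == live & series$day == d] / m0_live
    y <- series$butane_amount[series$treatment == sterile & series$day == d] / m0_st
    tt <- students_t_test(x, y)
    data.frame(day = d, R_live = rl, R_sterile = rs,
               biodegradation_pct = as.numeric(b),
               raw_difference = attr(b, "raw"),
               t_stat = tt$t, df = tt$df, p_value = tt$p,
               significant = tt$p < alpha)
  })
  do.call(rbind, rows)
}
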