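#' Linear induction fit for a reporter time course
#'
#' Fits \eqn{y = a + b t} by unweighted least squares to the specific
#' beta-galactosidase activities of one strain under one condition, using
#' only points at \eqn{t \ge} `window_start` minutes (default 60, past the
#' transient of regulator activation). By default the fit is performed on the
#' per-time mean across replicates; set `on = "replicates"` to fit all raw
#' points.
#'
#' When `shared_intercept_with` is supplied (typically the same strain's
#' uninduced course), one common intercept `a` is estimated jointly for both
#' courses with separate slopes, reflecting that both start from the same
#' basal expression level. The companion course's fit is attached as
#' `attr(fit, "companion")`.
#'
#' @param course data.frame with columns `time` (minutes) and `activity`
#'   (U/mg), optionally `replicate`.
#' @param window_start fit window start in minutes; points earlier than this
#'   are ignored.
#' @param shared_intercept_with optional second course fitted jointly with a
#'   common intercept.
#' @param on fit the per-time `"means"` (default) or all `"replicates"`.
#' @return An object of class `linear_fit`: list with `a`, `a_dev`, `b`,
#'   `b_dev` (estimates and standard errors), `regcoff` (percent, squared
#'   Pearson correlation of observed vs fitted times 100), `window_start`,
#'   and `n` (points used).
#' @examples
#' tc <- data.frame(time = seq(0, 180, 30), activity = 20 + 0.1 * seq(0, 180, 30))
#' fit_linear(tc)
#' @export
fit_linear <- function(course, window_start = 60, shared_intercept_with = NULL,
                       on = c("means", "replicates")) {
  on <- match.arg(on)
  d1 <- prepare_course(course, window_start, on)
  if (is.null(shared_intercept_with)) {
    if (length(unique(d1$time)) < 2L) {
      stop("need >= 2 distinct time points at t >= window_start", call. = FALSE)
    }
    fit <- lm(activity ~ time, data = d1)
    return(linear_fit_from_lm(fit, d1, window_start,
                              a_name = "(Intercept)", b_name = "time"))
  }
  d2 <- prepare_course(shared_intercept_with, window_start, on)
  if (length(unique(c(d1$time, d2$time))) < 2L || nrow(d1) + nrow(d2) < 3L) {
    stop("joint fit needs >= 3 points with >= 2 distinct times", call. = FALSE)
  }
  both <- rbind(cbind(d1, g = "one"), cbind(d2, g = "two"))
  both$t1 <- ifelse(both$g == "one", both$time, 0)
  both$t2 <- ifelse(both$g == "two", both$time, 0)
  joint <- lm(activity ~ t1 + t2, data = both)
  f1 <- linear_fit_from_lm(joint, d1, window_start, "(Intercept)", "t1")
  f2 <- linear_fit_from_lm(joint, d2, window_start, "(Intercept)", "t2")
  attr(f1, "companion") <- f2
  f1
}

prepare_course <- function(course, window_start, on) {
  if (!all(c("time", "activity") %in% names(course))) {
    stop("course must have columns 'time' and 'activity'", call. = FALSE)
  }
  d <- course[course$time >= window_start, c("time", "activity"), drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no points at t >= window_start (", window_start, " min)",
         call. = FALSE)
  }
  if (on == "means") {
    agg <- tapply(d$activity, d$time, mean)
    d <- data.frame(time = as.numeric(names(agg)), activity = as.numeric(agg))
  }
  d
}

linear_fit_from_lm <- function(fit, d, window_start, a_name, b_name) {
  est <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  fitted_d <- est[[a_name]] + est[[b_name]] * d$time
  structure(
    list(a = unname(est[[a_name]]), a_dev = unname(se[[a_name]]),
         b = unname(est[[b_name]]), b_dev = unname(se[[b_name]]),
         regcoff = regcoff_or_na(d$activity, fitted_d),
         window_start = window_start, n = nrow(d)),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit (t >= %g min, n = %d): a = %.4g +/- %.2g U/mg, b = %.4g +/- %.2g U/mg/min, RegCoff %.1f%%\n",
    x$window_start, x$n, x$a, x$a_dev, x$b, x$b_dev, x$regcoff))
  invisible(x)
}

#' Lag (liftoff) time of an induction time course
#'
#' Computes the delay before reporter activity starts to rise,
#' \deqn{t_{lag} = [y(t=0) - a + 60 b] / b,}
#' from the observed initial activity `y0` and a [fit_linear()] fit on the
#' window \eqn{t \ge 60} min. For data lying on the fitted line from t = 0 the
#' formula yields exactly 60 min; for exact piecewise-linear data flat until
#' time L (\eqn{L \ge 60}) and rising with slope b afterwards it yields
#' L + 60. Negative values are meaningful ("no detectable lag") and are kept
#' as signed numbers; [format_lag()] renders them as the sentinel `"<0"` for
#' reports.
#'
#' @param y0 observed specific activity at t = 0 (U/mg), typically the mean
#'   over replicates of the earliest time point (see [y_zero()]).
#' @param fit a `linear_fit` object.
#' @return Lag time in minutes (signed numeric).
#' @export
lag_time <- function(y0, fit) {
  stopifnot_scalar_number(y0, "y0")
  if (!inherits(fit, "linear_fit")) stop("'fit' must be a linear_fit")
  if (fit$b == 0) {
    stop("lag time undefined: fitted slope b is zero", call. = FALSE)
  }
  (y0 - fit$a + 60 * fit$b) / fit$b
}

#' Initial activity of a time course
#'
#' Mean observed activity at the earliest measured time point at or below
#' `t_max` minutes; used as \eqn{y(t=0)} in [lag_time()].
#'
#' @param course data.frame with `time` and `activity` columns.
#' @param t_max latest time (minutes) still counted as "initial"; default 5.
#' @return Mean activity (U/mg) at the earliest eligible time.
#' @export
y_zero <- function(course, t_max = 5) {
  early <- course[course$time <= t_max, , drop = FALSE]
  if (nrow(early) == 0L) {
    stop("no observations at t <= ", t_max, " min", call. = FALSE)
  }
  t0 <- min(early$time)
  mean(early$activity[early$time == t0])
}

#' Render lag times with the below-zero sentinel
#'
#' @param lag numeric lag time(s) in minutes.
#' @param digits digits for positive values.
#' @return Character vector; negative lags become `"<0"`.
#' @export
format_lag <- function(lag, digits = 0) {
  ifelse(lag < 0, "<0", formatC(round(lag, digits), format = "fg"))
}

#' Quadratic induction fit
#'
#' Fits \eqn{y = a + b t + c t^2} by least squares over the whole course
#' (per-time means by default). The quadratic term captures induction that
#' accelerates over time, the alternative description of delayed regulator
#' activation to a linear rise after a lag.
#'
#' @inheritParams fit_linear
#' @return An object of class `poly_fit`: `a`, `b`, `c` with `*_dev`
#'   standard errors, `regcoff` (percent), `n`.
#' @export
fit_polynomial <- function(course, on = c("means", "replicates")) {
  on <- match.arg(on)
  d <- prepare_course(course, window_start = -Inf, on = on)
  if (length(unique(d$time)) < 3L) {
    stop("need >= 3 distinct time points for a quadratic fit", call. = FALSE)
  }
  fit <- lm(activity ~ time + I(time^2), data = d)
  est <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  fitted_d <- est[[1]] + est[[2]] * d$time + est[[3]] * d$time^2
  structure(
    list(a = unname(est[[1]]), a_dev = unname(se[[1]]),
         b = unname(est[[2]]), b_dev = unname(se[[2]]),
         c = unname(est[[3]]), c_dev = unname(se[[3]]),
         regcoff = regcoff_or_na(d$activity, fitted_d), n = nrow(d)),
    class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf(
    "Quadratic fit (n = %d): a = %.4g +/- %.2g, b = %.4g +/- %.2g, c = %.4g +/- %.2g, RegCoff %.1f%%\n",
    x$n, x$a, x$a_dev, x$b, x$b_dev, x$c, x$c_dev, x$regcoff))
  invisible(x)
}

#' Slope ratio Q(b) between a mutant and the parent strain
#'
#' Ratio of the fitted induction slopes, \eqn{Q(b) = b_{mut} / b_{parent}},
#' measuring the mutant's regulatory output relative to the parent under the
#' same inducing condition. The ratio is flagged significant when the
#' distance statistic on the two slope estimates exceeds 1
#' (non-overlapping error bars; see [d_statistic()]).
#'
#' @param fit_mut,fit_parent `linear_fit` objects (or lists with `b` and
#'   `b_dev`) for mutant and parent.
#' @param n_mut,n_parent replicate counts behind each fit, used only for the
#'   significance label of the D comparison (default 3).
#' @return Object of class `qb_result`: `qb`, `d`, `significant`,
#'   `significance_label`.
#' @examples
#' mut <- list(b = 0.405, b_dev = 0.010)
#' parent <- list(b = 0.078, b_dev = 0.002)
#' qb(mut, parent)
#' @export
qb <- function(fit_mut, fit_parent, n_mut = 3, n_parent = 3) {
  if (fit_parent$b == 0) {
    stop("Q(b) undefined: parent slope is zero", call. = FALSE)
  }
  d <- d_statistic(measured_value(fit_mut$b, fit_mut$b_dev, n_mut),
                   measured_value(fit_parent$b, fit_parent$b_dev, n_parent))
  structure(
    list(qb = fit_mut$b / fit_parent$b, d = d$d,
         significant = d$d > 1, significance_label = d$significance_label),
    class = "qb_result")
}

#' @export
print.qb_result <- function(x, ...) {
  cat(sprintf("Q(b) = %.3g (D = %.3g, %s)\n", x$qb, x$d,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Regression coefficient (percent)
#'
#' Goodness-of-fit reported as 100 times the squared Pearson correlation
#' between observed and fitted values.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2).
#' @return Percent in \[0, 100\].
#' @export
regression_coefficient <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop("'observed' and 'fitted' must have equal length >= 2", call. = FALSE)
  }
  if (sd(observed) == 0) {
    stop("regression coefficient undefined: observed values are constant",
         call. = FALSE)
  }
  if (sd(fitted) == 0) return(0)
  100 * cor(observed, fitted)^2
}

# exactly constant observed data (e.g. a noise-free flat course) has no
# defined correlation; report NA in fit objects instead of failing
regcoff_or_na <- function(observed, fitted) {
  if (sd(observed) == 0) NA_real_ else regression_coefficient(observed, fitted)
}

#' Read a tidy time-course TSV
#'
#' Expected columns: `strain`, `condition`, `replicate`, `time_min`,
#' `activity_U_per_mg` (names as written by [write_time_course()]).
#'
#' @param file path to the TSV.
#' @return data.frame with canonical columns `strain`, `condition`,
#'   `replicate`, `time`, `activity`.
#' @export
read_time_course <- function(file) {
  tab <- read.delim(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "replicate", "time_min", "activity_U_per_mg")
  if (!all(need %in% names(tab))) {
    stop("time-course file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  data.frame(strain = tab$strain, condition = tab$condition,
             replicate = tab$replicate, time = tab$time_min,
             activity = tab$activity_U_per_mg, stringsAsFactors = FALSE)
}

#' Write a tidy time-course TSV
#'
#' @param course data.frame with `strain`, `condition`, `replicate`, `time`,
#'   `activity` columns.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_time_course <- function(course, file) {
  out <- data.frame(strain = course$strain, condition = course$condition,
                    replicate = course$replicate, time_min = course$time,
                    activity_U_per_mg = course$activity)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Fit report table for a set of strains
#'
#' Builds a per-strain report of the induced/uninduced linear fits with a
#' shared intercept: regression coefficients, intercept, slopes, lag times
#' (with the `"<0"` sentinel) and the slope ratio Q(b) against a parent
#' strain.
#'
#' @param courses data.frame of time courses (columns `strain`, `condition`,
#'   `replicate`, `time`, `activity`) holding exactly two conditions per
#'   strain.
#' @param parent name of the parent strain for Q(b); its induced slope is the
#'   denominator.
#' @param induced_condition value of `condition` marking the induced course;
#'   default the lexicographically later of the two conditions.
#' @param window_start fit window start (minutes).
#' @return data.frame with one row per strain and columns mirroring a
#'   kinetics summary table.
#' @export
fit_report <- function(courses, parent, induced_condition = NULL,
                       window_start = 60) {
  strains <- unique(courses$strain)
  conds <- sort(unique(courses$condition))
  if (length(conds) != 2L) {
    stop("fit_report expects exactly two conditions", call. = FALSE)
  }
  if (is.null(induced_condition)) induced_condition <- conds[2L]
  uninduced_condition <- setdiff(conds, induced_condition)
  one <- function(s) {
    ind <- courses[courses$strain == s & courses$condition == induced_condition, ]
    un <- courses[courses$strain == s & courses$condition == uninduced_condition, ]
    f_ind <- fit_linear(ind, window_start, shared_intercept_with = un)
    f_un <- attr(f_ind, "companion")
    data.frame(strain = s,
               regcoff_uninduced = f_un$regcoff, regcoff_induced = f_ind$regcoff,
               a = f_ind$a, a_dev = f_ind$a_dev,
               b_uninduced = f_un$b, b_uninduced_dev = f_un$b_dev,
               t_lag_uninduced = format_lag(lag_time(y_zero(un), f_un)),
               b_induced = f_ind$b, b_induced_dev = f_ind$b_dev,
               t_lag_induced = format_lag(lag_time(y_zero(ind), f_ind)),
               stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, lapply(strains, one))
  parent_row <- rep[rep$strain == parent, ]
  if (nrow(parent_row) != 1L) stop("parent strain not found", call. = FALSE)
  rep$qb <- vapply(seq_len(nrow(rep)), function(i) {
    qb(list(b = rep$b_induced[i], b_dev = rep$b_induced_dev[i]),
       list(b = parent_row$b_induced, b_dev = parent_row$b_induced_dev))$qb
  }, numeric(1))
  rep
}
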