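#' A measured value with its deviation and replicate count
#'
#' Light container for a mean, its deviation (error-bar half-width, e.g. a
#' standard deviation or fit standard error) and the number of replicates
#' behind it, as consumed by [d_statistic()].
#'
#' @param mean the mean value (any consistent unit).
#' @param dev the deviation, same unit, >= 0.
#' @param n number of replicates (integer >= 2).
#' @return Object of class `measured_value`.
#' @export
measured_value <- function(mean, dev, n = 3) {
  stopifnot_scalar_number(mean, "mean")
  stopifnot_scalar_number(dev, "dev")
  if (dev < 0) stop("'dev' must be >= 0", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  structure(list(mean = mean, dev = dev, n = as.integer(n)),
            class = "measured_value")
}

#' Distance statistic D for two measured values
#'
#' The distance statistic compares two means with error bars:
#' \deqn{D = |m_x - m_y| / (d_x + d_y).}
#' D > 1 means the deviation bars \eqn{[m \pm d]} do not intersect. With
#' deviations of similar magnitude, non-intersecting bars over n replicates
#' correspond to at least the significance level given by
#' [significance_level()] (95\% at n = 3, rising with n).
#'
#' @param x,y `measured_value` objects (or lists with `mean`, `dev`, `n`).
#' @return Object of class `d_result`: `d`, `n_effective` (the smaller
#'   replicate count), `significance_label`.
#' @examples
#' d_statistic(measured_value(10, 1, n = 3), measured_value(14, 2, n = 3))
#' @export
d_statistic <- function(x, y) {
  if (x$dev + y$dev <= 0) {
    stop("D undefined: both deviations are zero", call. = FALSE)
  }
  d <- abs(x$mean - y$mean) / (x$dev + y$dev)
  n_eff <- min(x$n, y$n)
  structure(list(d = d, n_effective = as.integer(n_eff),
                 significance_label = significance_level(d, n_eff)),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.3g (n = %d): %s\n", x$d, x$n_effective,
              x$significance_label))
  invisible(x)
}

#' Significance label for a D value at a given replicate count
#'
#' Maps a distance statistic and replicate count to the significance level of
#' a difference with non-intersecting error bars: at n = 3 the level is at
#' least 95\%, at n = 4 at least 97.5\%, at n = 5 at least 99\% and at n = 8
#' at least 99.9\%. Counts between the anchors inherit the level of the next
#' lower anchor (conservative); n = 2 is floored at the n = 3 label. D <= 1
#' is always `"<95\%"` (overlapping bars).
#'
#' @param d distance statistic, >= 0.
#' @param n replicate count, integer >= 2.
#' @return One of `"<95%"`, `">=95%"`, `">=97.5%"`, `">=99%"`, `">=99.9%"`.
#' @examples
#' significance_level(1.82, 6)
#' significance_level(0.73, 6)
#' @export
significance_level <- function(d, n) {
  stopifnot_scalar_number(d, "d")
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  if (d <= 1) return("<95%")
  if (n >= 8) ">=99.9%" else if (n >= 5) ">=99%" else if (n >= 4) ">=97.5%" else ">=95%"
}

#' Two-sample Student's t test on summary statistics
#'
#' Secondary comparison method: Welch's t test computed from the means,
#' standard deviations and replicate counts of two groups. The distance
#' statistic [d_statistic()] is the primary method; the t test is offered
#' for users who want a conventional p value.
#'
#' @param x,y `measured_value` objects whose `dev` is a standard deviation.
#' @return list with `t`, `df` (Welch-Satterthwaite) and `p_value`
#'   (two-sided).
#' @export
t_statistic <- function(x, y) {
  vx <- x$dev^2 / x$n
  vy <- y$dev^2 / y$n
  if (vx + vy <= 0) stop("t undefined: both deviations are zero", call. = FALSE)
  t <- (x$mean - y$mean) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (x$n - 1) + vy^2 / (y$n - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Compare two columns of measured values from a table
#'
#' Reads triples (mean, dev, n) for two groups and returns the D comparison
#' per row, for use from scripts and the command line.
#'
#' @param tab data.frame with columns `mean_x`, `dev_x`, `n_x`, `mean_y`,
#'   `dev_y`, `n_y`.
#' @return The input with `d` and `significance` columns appended.
#' @export
compare_table <- function(tab) {
  res <- lapply(seq_len(nrow(tab)), function(i) {
    d_statistic(measured_value(tab$mean_x[i], tab$dev_x[i], tab$n_x[i]),
                measured_value(tab$mean_y[i], tab$dev_y[i], tab$n_y[i]))
  })
  tab$d <- vapply(res, `[[`, numeric(1), "d")
  tab$significance <- vapply(res, `[[`, character(1), "significance_label")
  tab
}
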