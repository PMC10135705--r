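#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function from right-censored
#' follow-up, computed from first principles. At each distinct event time
#' `t_i` with `n_i` cases at risk and `d_i` events, the curve drops by the
#' factor `1 - d_i/n_i`; censored times thin the subsequent risk set but
#' contribute no factor. A censoring tied with an event at the same time
#' is handled events-first: the censored case still counts in the risk set
#' at that time (the standard convention).
#'
#' @param time Nonnegative follow-up times (months in the disease-free
#'   survival analyses, but any consistent unit works).
#' @param event Event indicators: 1 = progression/relapse observed,
#'   0 = censored.
#' @return Data frame with class `"km_curve"`: one row per distinct
#'   observed time with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))   # S(1) = 2/3, S(3) = 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L)
    stop("no survival records", call. = FALSE)
  if (length(time) != length(event))
    stop("'time' and 'event' lengths differ", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("follow-up times must be finite and nonnegative", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)", call. = FALSE)
  ut <- sort(unique(time))
  n <- length(time)
  surv <- 1
  out <- data.frame(time = ut, n_risk = NA_integer_, n_event = NA_integer_,
                    n_censor = NA_integer_, survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    c_ <- sum(time == ut[i] & event == 0)
    if (d > 0) surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c_
    out$survival[i] <- surv
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at given times
#'
#' Evaluates a Kaplan-Meier curve as a right-continuous step function;
#' times before the first observed time return 1.
#'
#' @param curve A `"km_curve"` from [km_estimate()].
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group logrank test
#'
#' The standard logrank test comparing censored survival between two
#' groups, computed from first principles. At each distinct event time
#' with `d` events, `n` cases at risk overall and `n_a` in group `a`, the
#' expected events in `a` are `d * n_a / n` and the variance is the
#' hypergeometric `d * (n - d) / (n - 1) * n_a * n_b / n^2`. The statistic
#' `(O_a - E_a)^2 / V` is referred to the chi-square distribution with one
#' degree of freedom; the p-value is the upper tail.
#'
#' @param time Follow-up times for all cases.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level grouping vector (factor or character) aligned
#'   with `time`.
#' @return List with class `"logrank_test"`: `chi_square`, `p_value`,
#'   `observed` and `expected` event counts per group, and `n` per group.
#' @examples
#' lr <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6),
#'                    rep(c("a", "b"), each = 3))
#' lr$p_value
#' @export
logrank_test <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("'time', 'event' and 'group' lengths differ", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("follow-up times must be finite and nonnegative", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)", call. = FALSE)
  group <- as.character(group)
  levs <- sort(unique(group))
  if (length(levs) != 2L)
    stop("logrank test requires exactly 2 groups; got ", length(levs),
         call. = FALSE)
  if (sum(event) == 0L)
    stop("no events in either group: logrank statistic undefined",
         call. = FALSE)
  a <- group == levs[1]
  etimes <- sort(unique(time[event == 1]))
  O_a <- 0; E_a <- 0; V <- 0
  for (t in etimes) {
    at <- time >= t
    n <- sum(at)
    n_a <- sum(at & a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & a)
    O_a <- O_a + d_a
    E_a <- E_a + d * n_a / n
    if (n > 1)
      V <- V + d * (n - d) / (n - 1) * n_a * (n - n_a) / n^2
  }
  chi <- if (V > 0) (O_a - E_a)^2 / V else 0
  total <- sum(event)
  res <- list(
    chi_square = chi,
    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    observed = stats::setNames(c(O_a, total - O_a), levs),
    expected = stats::setNames(c(E_a, total - E_a), levs),
    n = stats::setNames(c(sum(a), sum(!a)), levs)
  )
  class(res) <- "logrank_test"
  res
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group logrank test\n")
  tab <- data.frame(n = x$n, observed = x$observed,
                    expected = round(x$expected, 3))
  print(tab)
  cat("chi-square =", format(x$chi_square, digits = 6),
      "on 1 df, p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Step-curve plot of one or two Kaplan-Meier curves
#'
#' @param curves Named list of `"km_curve"` objects (typically
#'   `list(upper = ..., lower = ...)`).
#' @param main,xlab,ylab Usual plot annotations.
#' @param col Line colours recycled over curves.
#' @return Invisibly, `curves`.
#' @export
plot_km <- function(curves, main = "Disease-free survival",
                    xlab = "Months", ylab = "Survival probability",
                    col = c("black", "grey50")) {
  stopifnot(is.list(curves), length(curves) >= 1)
  xmax <- max(vapply(curves, function(k) max(k$time), numeric(1)))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), main = main,
       xlab = xlab, ylab = ylab)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$survival)), col = col[i],
                    do.points = FALSE)
  }
  if (!is.null(names(curves)))
    graphics::legend("topright", legend = names(curves), col = col, lty = 1)
  invisible(curves)
}
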