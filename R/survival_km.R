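# Kaplan-Meier product-limit estimation and the Mantel-Cox log-rank test,
# implemented from first principles for the post-PDT survival endpoint.

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood variance. Ties between
#' deaths and censorings at the same time follow the usual convention:
#' censored subjects remain in the risk set for deaths at that time. The
#' median is the first time at which S(t) <= 0.5 (so S hitting exactly 0.5
#' returns that time, which is how half-day medians arise with even n).
#'
#' @param time positive event/censoring times.
#' @param event 1/TRUE for death, 0/FALSE for censored.
#' @return Object of class `pdt_km`: per-death-time table (`time`, `n_risk`,
#'   `n_event`, `surv`, `se`), `median` (NA when S never reaches 0.5 or no
#'   events occur), `n`, `n_events`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1)) # S(1) = 2/3, S(3) = 0
km_estimate <- function(time, event) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time }
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be positive", call. = FALSE)
  if (!all(event %in% c(0L, 1L)))
    stop("'event' must be 0/1 (censored/death)", call. = FALSE)
  n <- length(time)
  dt <- sort(unique(time[event == 1L]))
  if (length(dt) == 0L) {
    return(structure(list(table = data.frame(time = numeric(0),
                                             n_risk = integer(0),
                                             n_event = integer(0),
                                             surv = numeric(0),
                                             se = numeric(0)),
                          median = NA_real_, n = n, n_events = 0L),
                     class = "pdt_km"))
  }
  n_risk <- vapply(dt, function(t) sum(time >= t), 0L)
  n_event <- vapply(dt, function(t) sum(time == t & event == 1L), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se <- surv * sqrt(gw)
  se[!is.finite(se)] <- NA_real_ # S = 0 with exhausted risk set
  # tolerance so S(t) landing on 0.5 up to cumprod rounding counts as reached
  hit <- surv <= 0.5 * (1 + 1e-9)
  med <- if (any(hit)) dt[which(hit)[1]] else NA_real_
  structure(list(table = data.frame(time = dt, n_risk = n_risk,
                                    n_event = n_event, surv = surv, se = se),
                 median = med, n = n, n_events = sum(event)),
            class = "pdt_km")
}

#' @export
print.pdt_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
summary.pdt_km <- function(object, ...) {
  print(object)
  print(object$table, row.names = FALSE)
  invisible(object$table)
}

#' @export
plot.pdt_km <- function(x, xlab = "time [days]", ylab = "S(t)", ...) {
  tb <- x$table
  plot(c(0, tb$time), c(1, tb$surv), type = "s", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Survival function value at given times
#'
#' @param km a [km_estimate()].
#' @param t times.
#' @return S(t) (right-continuous step function).
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "pdt_km"))
  tb <- km$table
  vapply(t, function(ti) {
    k <- sum(tb$time <= ti)
    if (k == 0L) 1 else tb$surv[k]
  }, 0)
}

#' Mantel-Cox log-rank test for two arms
#'
#' Observed-minus-expected deaths in arm A over the pooled distinct death
#' times, with the hypergeometric variance
#' V_j = d_j (n_Aj / n_j)(1 - n_Aj / n_j)(n_j - d_j)/(n_j - 1);
#' chi^2 = (O - E)^2 / V on 1 df, two-sided p. When every death occurs at a
#' single time with no variance the test is undefined and a sentinel is
#' returned (`statistic = NA`).
#'
#' @param time,event,arm vectors, or a data frame with those columns as the
#'   first argument.
#' @return Object of class `pdt_logrank`: `statistic`, `p_value`,
#'   `observed`, `expected` (for the first arm level), `arms`.
#' @export
logrank_test <- function(time, event = NULL, arm = NULL) {
  if (is.data.frame(time)) {
    arm <- time$arm; event <- time$event; time <- time$time
  }
  event <- as.integer(event)
  arm <- as.factor(arm)
  if (nlevels(arm) != 2L)
    stop("logrank_test compares exactly two arms; got ", nlevels(arm),
         call. = FALSE)
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  a <- arm == levels(arm)[1]
  dt <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (t in dt) {
    at <- time >= t
    n_j <- sum(at); n_aj <- sum(at & a)
    d_j <- sum(time == t & event == 1L)
    d_aj <- sum(time == t & event == 1L & a)
    O <- O + d_aj
    E <- E + d_j * n_aj / n_j
    if (n_j > 1L)
      V <- V + d_j * (n_aj / n_j) * (1 - n_aj / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (V <= 0 && abs(O - E) < 1e-12) {
    stat <- 0; p <- 1
  } else if (V <= 0) {
    stat <- NA_real_; p <- NA_real_
  } else {
    stat <- (O - E)^2 / V
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, observed = O, expected = E,
                 variance = V, arms = levels(arm)),
            class = "pdt_logrank")
}

#' @export
print.pdt_logrank <- function(x, ...) {
  cat(sprintf("Mantel-Cox log-rank: %s vs %s\n", x$arms[1], x$arms[2]))
  if (is.na(x$statistic))
    cat("  undefined (zero variance)\n")
  else
    cat(sprintf("  O = %g, E = %.3g, chi-square = %.4g (1 df), p = %.4g\n",
                x$observed, x$expected, x$statistic, x$p_value))
  invisible(x)
}

#' Pairwise log-rank comparisons across arms
#'
#' @param records data frame with `time`, `event`, `arm`.
#' @param adjust p-value adjustment (`"none"`, the reporting default, or any
#'   [stats::p.adjust()] method such as `"holm"`).
#' @return Data frame of arm pairs with chi-square and p.
#' @export
pairwise_logrank <- function(records, adjust = "none") {
  arms <- unique(as.character(records$arm))
  if (length(arms) < 2L) stop("need >= 2 arms", call. = FALSE)
  pairs <- utils::combn(arms, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    d <- records[records$arm %in% pairs[, i], ]
    lr <- logrank_test(d)
    data.frame(arm_a = pairs[1, i], arm_b = pairs[2, i],
               chisq = lr$statistic, p_value = lr$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Read survival records from CSV
#'
#' Expects columns `subject`, `arm`, `time_days`, `event`.
#'
#' @param path CSV file.
#' @return Data frame with standardized `time`, `event`, `arm` columns.
#' @export
read_survival_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "arm", "time_days", "event")
  if (!all(req %in% names(d)))
    stop("survival CSV needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  data.frame(subject = d$subject, arm = d$arm, time = d$time_days,
             event = d$event, stringsAsFactors = FALSE)
}
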