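# Time-to-onset summaries and two-parameter Weibull maximum likelihood with
# failure-type classification.

.tto_bin_breaks <- c(0, 30, 90, 180, 360, Inf)
.tto_bin_labels <- c("1-30", "31-90", "91-180", "181-360", ">360")

#' Summarise time-to-onset samples
#'
#' Median and interquartile range use linear-interpolation (type 7)
#' quantiles. Counts and percentages are reported over the bins 1-30,
#' 31-90, 91-180, 181-360 and >360 days.
#'
#' @param days Vector of positive integer onset delays (days).
#' @return Tibble of class `pv_tto_summary` with one row (`n`, `median`,
#'   `q1`, `q3`, `min`, `max`) and the bin table in attribute `bins`
#'   (`bin`, `count`, `pct`).
#' @export
summarize_tto <- function(days) {
  days <- days[!is.na(days)]
  if (length(days) == 0) {
    out <- tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, min = NA_real_, max = NA_real_)
    attr(out, "bins") <- tibble::tibble(bin = .tto_bin_labels, count = 0L,
                                        pct = NA_real_)
    class(out) <- c("pv_tto_summary", class(out))
    return(out)
  }
  stopifnot(all(days > 0))
  q <- quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bins <- table(cut(days, breaks = .tto_bin_breaks,
                    labels = .tto_bin_labels, right = TRUE))
  out <- tibble::tibble(n = length(days), median = q[2], q1 = q[1],
                        q3 = q[3], min = min(days), max = max(days))
  attr(out, "bins") <- tibble::tibble(
    bin = .tto_bin_labels,
    count = as.integer(bins),
    pct = 100 * as.integer(bins) / length(days))
  class(out) <- c("pv_tto_summary", class(out))
  out
}

#' Bin table of a time-to-onset summary
#'
#' @param summary A `pv_tto_summary` from [summarize_tto()].
#' @return Tibble with `bin`, `count`, `pct`.
#' @export
tto_bins <- function(summary) {
  stopifnot(inherits(summary, "pv_tto_summary"))
  attr(summary, "bins")
}

# Weibull negative log-likelihood on log-parameters (log shape, log scale).
.weibull_nll <- function(logpar, x) {
  val <- suppressWarnings(
    -sum(dweibull(x, shape = exp(logpar[1]), scale = exp(logpar[2]),
                  log = TRUE)))
  if (!is.finite(val)) return(1e10)  # steer the search back in-range
  val
}

#' Fit a two-parameter Weibull distribution to onset delays
#'
#' Maximum likelihood for the density
#' \deqn{f(t) = (\beta/\alpha)(t/\alpha)^{\beta-1}
#'   \exp\{-(t/\alpha)^\beta\}}
#' via quasi-Newton optimisation on the log-parameters. 95% Wald intervals
#' come from the observed information on the log scale, back-transformed
#' (so they are positive and contain the point estimates by construction).
#' Failure type: `early` when the shape CI upper bound is below 1 (hazard
#' decreasing over time), `wear_out` when the lower bound exceeds 1,
#' otherwise `random`.
#'
#' @param days Vector of positive onset delays, length >= 3, not all equal.
#' @return Object of class `pv_weibull_fit`: `n`, `shape`, `scale`,
#'   `shape_ci`, `scale_ci`, `loglik`, `failure_type`, `data`.
#' @export
fit_weibull <- function(days) {
  x <- as.numeric(days[!is.na(days)])
  if (length(x) < 3) stop("need at least 3 onset values", call. = FALSE)
  if (any(x <= 0)) stop("onset values must be positive", call. = FALSE)
  if (max(x) == min(x)) {
    stop("all onset values are equal; the Weibull MLE does not exist",
         call. = FALSE)
  }
  # moment-style start from the Gumbel representation of log(X)
  s_log <- sd(log(x))
  shape0 <- max(1.2 / s_log, 1e-3)
  scale0 <- exp(mean(log(x)) + 0.5772 / shape0)
  opt <- optim(log(c(shape0, scale0)), .weibull_nll, x = x,
               method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("Weibull likelihood optimisation did not converge", call. = FALSE)
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) {
    stop("observed information is singular; no Wald interval available",
         call. = FALSE)
  }
  se_log <- sqrt(diag(vc))
  est <- exp(opt$par)
  ci <- rbind(exp(opt$par[1] + c(-1, 1) * 1.96 * se_log[1]),
              exp(opt$par[2] + c(-1, 1) * 1.96 * se_log[2]))
  failure_type <- if (ci[1, 2] < 1) {
    "early"
  } else if (ci[1, 1] > 1) {
    "wear_out"
  } else {
    "random"
  }
  structure(list(n = length(x), shape = est[1], scale = est[2],
                 shape_ci = ci[1, ], scale_ci = ci[2, ],
                 vcov_log = vc, loglik = -opt$value,
                 failure_type = failure_type, data = x),
            class = "pv_weibull_fit")
}

#' @export
print.pv_weibull_fit <- function(x, ...) {
  cat("<pv_weibull_fit>\n")
  cat(sprintf("  n = %d\n", x$n))
  cat(sprintf("  shape (beta) = %.3f  [%.3f, %.3f]\n",
              x$shape, x$shape_ci[1], x$shape_ci[2]))
  cat(sprintf("  scale (alpha) = %.2f days  [%.2f, %.2f]\n",
              x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  failure type: %s\n", x$failure_type))
  invisible(x)
}

#' @describeIn fit_weibull One row per parameter with estimate and 95% CI.
#' @param x A `pv_weibull_fit`.
#' @param ... Unused.
#' @method tidy pv_weibull_fit
#' @export
tidy.pv_weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    conf.low = c(x$shape_ci[1], x$scale_ci[1]),
    conf.high = c(x$shape_ci[2], x$scale_ci[2]))
}

#' @describeIn fit_weibull One-row model summary (n, log-likelihood,
#'   failure type, median onset).
#' @method glance pv_weibull_fit
#' @export
glance.pv_weibull_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$loglik,
                 failure_type = x$failure_type,
                 median_days = unname(median(x$data)))
}
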