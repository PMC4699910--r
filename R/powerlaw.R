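#' Draw from a continuous Pareto (pure power-law) distribution
#'
#' Density `p(x) = (alpha-1)/xmin * (x/xmin)^-alpha` for `x >= xmin`,
#' `alpha > 1`.
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin lower cut-off (> 0).
#' @return numeric vector of length `n`.
#' @export
rpareto <- function(n, alpha, xmin = 1) {
  stopifnot(alpha > 1, xmin > 0)
  xmin * stats::runif(n)^(-1 / (alpha - 1))
}

.step_values <- function(steps) {
  s <- if (is.data.frame(steps)) steps$length else as.numeric(steps)
  if (is.null(s)) stop("`steps` must be a step_series or a numeric vector")
  s[is.finite(s)]
}

#' Maximum-likelihood power-law exponent
#'
#' Continuous MLE for the tail exponent:
#' `alpha_hat = 1 + n / sum(log(S_j / xmin))` over the `n` tail values
#' `S_j >= xmin`. Scale-invariant: rescaling the tail and `xmin` together
#' leaves the estimate unchanged.
#'
#' @param tail numeric tail sample, all values `>= xmin`.
#' @param xmin lower cut-off (> 0).
#' @return estimated exponent (> 1).
#' @export
mle_alpha <- function(tail, xmin) {
  tail <- .step_values(tail)
  if (length(tail) < 2L) stop("need at least 2 tail values")
  if (!is.numeric(xmin) || xmin <= 0) stop("`xmin` must be > 0")
  if (any(tail < xmin * (1 - 1e-12))) stop("all tail values must be >= xmin")
  s <- sum(log(tail / xmin))
  if (s <= 0)
    stop(structure(class = c("wormpath_divergent_fit", "error", "condition"),
                   list(message = "divergent fit: all tail values equal xmin",
                        call = sys.call(-1))))
  1 + length(tail) / s
}

# Kolmogorov-Smirnov distance between the empirical CDF of a tail sample and
# the fitted power-law CDF F(x) = 1 - (x/xmin)^(1-alpha), evaluated at the
# sample points on both sides of each empirical jump.
.ks_distance <- function(tail, xmin, alpha) {
  x <- sort(tail)
  n <- length(x)
  Fm <- 1 - (x / xmin)^(1 - alpha)
  max(pmax(abs(Fm - (seq_len(n) - 1) / n), abs(Fm - seq_len(n) / n)))
}

#' Estimate the power-law lower cut-off
#'
#' Few empirical samples follow a power law over their whole range; the fit
#' applies only above some minimum step length. Each distinct observed step
#' value whose tail retains at least `min_tail` points is tried as a
#' candidate cut-off: the exponent is fitted on the tail by maximum
#' likelihood and the Kolmogorov-Smirnov distance between the empirical tail
#' distribution and the fitted model computed; the candidate minimizing the
#' distance is returned, ties broken toward the smaller cut-off (larger tail,
#' more statistical power).
#'
#' @param steps a `step_series` or numeric vector of step lengths (mm).
#' @param min_tail smallest admissible tail size (default 10; also the floor
#'   on the number of positive steps required).
#' @return list with `xmin`, `alpha`, `ks_distance`, `n_tail`, and
#'   `candidates` (data.frame of the scanned grid).
#' @export
estimate_xmin <- function(steps, min_tail = 10L) {
  s <- .step_values(steps)
  s <- s[s > 0]
  if (length(s) < min_tail)
    stop("insufficient data: need at least ", min_tail, " positive step lengths")
  cand <- sort(unique(s))
  n_tail_c <- vapply(cand, function(x) sum(s >= x), numeric(1))
  cand <- cand[n_tail_c >= min_tail]
  if (length(cand) == 0L) stop("insufficient data: no candidate retains ", min_tail, " tail points")
  res <- data.frame(xmin = cand, alpha = NA_real_, ks = NA_real_, n_tail = NA_integer_)
  for (i in seq_along(cand)) {
    tail <- s[s >= cand[[i]]]
    a <- tryCatch(mle_alpha(tail, cand[[i]]), wormpath_divergent_fit = function(e) NA_real_)
    res$n_tail[[i]] <- length(tail)
    if (is.na(a)) next
    res$alpha[[i]] <- a
    res$ks[[i]] <- .ks_distance(tail, cand[[i]], a)
  }
  if (all(is.na(res$ks)))
    stop(structure(class = c("wormpath_divergent_fit", "error", "condition"),
                   list(message = "divergent fit: all step lengths identical", call = sys.call(-1))))
  best <- which(res$ks == min(res$ks, na.rm = TRUE))[[1L]]  # smallest xmin on ties
  list(xmin = res$xmin[[best]], alpha = res$alpha[[best]], ks_distance = res$ks[[best]],
       n_tail = res$n_tail[[best]], candidates = res)
}

#' Classify a walk from its power-law exponent
#'
#' The Levy regime `1 < alpha <= 3` is where the step-length distribution has
#' a normalizable power-law tail with divergent variance: clusters of short
#' moves interspersed with rare long relocations. `alpha > 3` has finite
#' variance and converges to Brownian motion; `alpha <= 1` is not
#' normalizable and resembles ballistic (straight-line) movement.
#'
#' @param alpha finite numeric exponent(s).
#' @return character vector: `"ballistic"`, `"levy"` or `"brownian"`.
#' @export
classify_walk <- function(alpha) {
  if (any(!is.finite(alpha))) stop("`alpha` must be finite")
  ifelse(alpha <= 1, "ballistic", ifelse(alpha <= 3, "levy", "brownian"))
}

#' Fit a truncated power law to step lengths
#'
#' Estimates the lower cut-off by KS minimization (unless `xmin` is fixed),
#' fits the exponent on the tail by maximum likelihood, and classifies the
#' walk. Returns a fitted-model object with the usual methods (`print`,
#' `summary`, `coef`, `plot`).
#'
#' @param steps a `step_series` or numeric vector of step lengths (mm).
#' @param xmin optional fixed lower cut-off; skips estimation.
#' @param min_tail smallest admissible tail size for cut-off candidates.
#' @param window_minutes optionally restrict to steps whose end time falls in
#'   the first `window_minutes` minutes (requires a `step_series` with
#'   times).
#' @return object of class `powerlaw_fit`: list with `alpha`, `xmin`,
#'   `n_tail`, `ks_distance`, `n_total`, `min_step`, `max_step`,
#'   `length_min` (recording length in minutes, if times available),
#'   `walk_class`, `steps` (the step lengths used).
#' @export
fit_steps <- function(steps, xmin = NULL, min_tail = 10L, window_minutes = NULL) {
  length_min <- NA_real_
  if (is.data.frame(steps)) {
    if (!is.null(steps$t_end)) {
      t0 <- min(steps$t_start)
      length_min <- (max(steps$t_end) - t0) / 60
      if (!is.null(window_minutes))
        steps <- steps[steps$t_end - t0 <= window_minutes * 60, , drop = FALSE]
    } else if (!is.null(window_minutes)) {
      stop("`window_minutes` requires a step series with times")
    }
  } else if (!is.null(window_minutes)) {
    stop("`window_minutes` requires a step series with times")
  }
  s <- .step_values(steps)
  s <- s[s > 0]
  if (is.null(xmin)) {
    est <- estimate_xmin(s, min_tail = min_tail)
  } else {
    tail <- s[s >= xmin]
    est <- list(xmin = xmin, alpha = mle_alpha(tail, xmin),
                ks_distance = .ks_distance(tail, xmin, mle_alpha(tail, xmin)),
                n_tail = length(tail))
  }
  structure(list(alpha = est$alpha, xmin = est$xmin, n_tail = est$n_tail,
                 ks_distance = est$ks_distance, n_total = length(s),
                 min_step = min(s), max_step = max(s),
                 length_min = length_min,
                 walk_class = classify_walk(est$alpha), steps = s),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, digits = 3, ...) {
  cat("Truncated power-law fit to step lengths\n")
  cat(sprintf("  alpha = %.*f, xmin = %.*f mm (KS distance %.*f)\n",
              digits, x$alpha, digits, x$xmin, digits, x$ks_distance))
  cat(sprintf("  tail n = %d of %d steps [%.3f, %.3f] mm\n",
              x$n_tail, x$n_total, x$min_step, x$max_step))
  cat(sprintf("  walk class: %s\n", x$walk_class))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(alpha = object$alpha, xmin = object$xmin)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  out <- data.frame(length_min = object$length_min, n_step = object$n_total,
                    min_step = object$min_step, max_step = object$max_step,
                    est_xmin = object$xmin, n_tail = object$n_tail,
                    est_alpha = object$alpha, distance = object$ks_distance,
                    walk_class = object$walk_class)
  class(out) <- c("summary.powerlaw_fit", "data.frame")
  out
}

#' @export
print.summary.powerlaw_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Empirical and fitted CCDF table for log-log plotting
#'
#' Complementary cumulative distribution of the tail sample, `P(S >= x)`,
#' alongside the fitted model CCDF `(x/xmin)^(1-alpha)`; both equal 1 at
#' `xmin` by construction.
#'
#' @param fit a `powerlaw_fit`.
#' @return data.frame: `x`, `ccdf_empirical`, `ccdf_model`.
#' @export
ccdf_table <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  tail <- sort(fit$steps[fit$steps >= fit$xmin])
  n <- length(tail)
  data.frame(x = tail,
             ccdf_empirical = (n - seq_len(n) + 1) / n,
             ccdf_model = (tail / fit$xmin)^(1 - fit$alpha))
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  tab <- ccdf_table(x)
  graphics::plot(tab$x, tab$ccdf_empirical, log = "xy", pch = 20, cex = 0.6,
                 xlab = "step length (mm)", ylab = "CCDF", ...)
  graphics::lines(tab$x, tab$ccdf_model, col = "red3", lwd = 2)
  graphics::legend("bottomleft", bty = "n",
                   legend = c("empirical", sprintf("model (alpha = %.2f)", x$alpha)),
                   pch = c(20, NA), lty = c(NA, 1), col = c("black", "red3"))
  invisible(x)
}
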