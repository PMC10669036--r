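#' Average sample width
#'
#' The sample width entering the peel-tension normalization is the
#' arithmetic mean of the width measurements taken along the sample (five
#' locations in the standard protocol).
#'
#' @param widths vector of width measurements, meters; non-empty, all
#'   positive.
#' @return mean width, meters.
#' @examples
#' mean_width(c(2.8, 3.0, 3.2, 3.0, 3.0) * 1e-3)
#' @export
mean_width <- function(widths) {
  if (length(widths) < 1)
    stop("`widths` must be non-empty", call. = FALSE)
  if (!all(is.finite(widths)) || any(widths <= 0))
    stop("`widths` must all be positive and finite", call. = FALSE)
  mean(widths)
}

#' Peel tension from a force trace
#'
#' Converts the recorded delamination force to peel tension per unit width,
#' \eqn{T_p = T / w}, with `w` the mean of the record's width measurements.
#'
#' @param record a [peel_record()].
#' @return numeric vector of tension values, N/m, same length as the trace.
#' @export
peel_tension <- function(record) {
  stopifnot(inherits(record, "peel_record"))
  record$force / mean_width(record$widths)
}

#' Locate the pre-failure fit window of a peel trace
#'
#' Real traces end in a sudden drop when the specimen tears apart; the
#' sigmoid model has no branch for that drop, so fitting is restricted to
#' the window before it. The window ends at the first point where the
#' tension falls below `drop_fraction` of its running maximum. Two
#' refinements keep the rule robust on noisy recordings: drops are only
#' recognized once the running maximum has reached `min_level_frac` of the
#' global maximum (sensor noise around the near-zero start, or ordinary
#' scatter on the rise, cannot trigger a spurious cut), and the window end
#' is then walked back across the strictly decreasing failure shoulder so
#' that the fitted points stop at the failure onset rather than partway
#' down the drop.
#'
#' @param tension numeric tension series, N/m (length >= 10).
#' @param drop_fraction drop threshold as a fraction of the running maximum,
#'   in (0, 1).
#' @param min_level_frac running-maximum level (fraction of the global
#'   maximum) below which drops are ignored.
#' @return integer vector `c(start, end)` (1-based, inclusive); `end` equals
#'   the series length when no failure drop is found.
#' @export
truncate_at_failure <- function(tension, drop_fraction = 0.5,
                                min_level_frac = 0.6) {
  if (length(tension) < 10)
    stop("`tension` must have at least 10 points", call. = FALSE)
  check_number(drop_fraction, "drop_fraction")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("`drop_fraction` must be in (0, 1)", call. = FALSE)
  n <- length(tension)
  rm <- cummax(tension)
  armed <- rm >= min_level_frac * max(tension)
  below <- armed & tension < drop_fraction * rm
  # a failure drop is sustained: require three consecutive sub-threshold
  # points (or fewer at the very end of the trace) so an isolated noise dip
  # cannot truncate the trace
  sustained <- below &
    c(below[-1], TRUE) &
    c(below[-(1:2)], TRUE, TRUE)
  hit <- which(sustained)
  end <- if (length(hit)) hit[1] - 1L else n
  # back off the monotone failure shoulder above the drop threshold
  while (end > 1 && end < length(tension) &&
         tension[end] < tension[end - 1]) end <- end - 1L
  c(start = 1L, end = as.integer(end))
}

#' Fit the sigmoid peel-tension model
#'
#' Least-squares fit of \eqn{T_p(t) = S_d / (1 + a e^{-b (t - c)})} over a
#' fit window, via Levenberg--Marquardt ([minpack.lm::nlsLM()]).
#'
#' The model as written is over-parameterized: `a` and `c` enter the curve
#' only through `a * exp(b * c)`, so only `S_d`, `b` and the half-maximum
#' time `m = c + log(a) / b` are identifiable from data. The fit therefore
#' optimizes `(S_d, b, m)` and reports the canonical representative
#' `a = 1`, `c = m` (at `t = c` the fitted tension is `S_d / 2`). Any other
#' `(a, c)` pair on the ridge describes the same curve.
#'
#' Starting values follow standard logistic heuristics: `S_d` from the 95th
#' percentile of the windowed tension, `m` from the half-maximum crossing,
#' `b = 4 / (t90 - t10)` from the 10--90% rise interval. Bounds keep the
#' optimizer in the physically meaningful branch: `S_d` in (0, 10 x max
#' tension], `b` in (0, 100], `m` unconstrained. Non-convergence is
#' reported via `converged = FALSE`, never silently imputed.
#'
#' @param time,tension numeric series of equal length.
#' @param window integer `c(start, end)` window (1-based, inclusive);
#'   default the whole series. Must contain at least 5 points.
#' @param max_iter maximum optimizer iterations.
#' @return a `sigmoid_fit` list with elements `S_d`, `a`, `b`, `c`, `rss`,
#'   `n_points`, `converged`, `fit_window` and `message`.
#' @examples
#' t <- seq(0, 60, 0.1)
#' y <- sigmoid_tension(t, 20, 50, 0.5, 10)
#' fit_sigmoid(t, y)$S_d
#' @export
fit_sigmoid <- function(time, tension, window = NULL, max_iter = 200) {
  stopifnot(length(time) == length(tension))
  if (is.null(window)) window <- c(1L, length(time))
  window <- as.integer(window)
  if (window[1] < 1 || window[2] > length(time) || window[2] < window[1])
    stop("`window` out of trace bounds", call. = FALSE)
  idx <- window[1]:window[2]
  if (length(idx) < 5)
    stop("fit window must contain at least 5 points", call. = FALSE)
  t <- time[idx]; y <- tension[idx]
  if (!all(is.finite(y))) stop("`tension` must be finite", call. = FALSE)

  failed <- function(msg) structure(
    list(S_d = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
         rss = NA_real_, n_points = length(idx), converged = FALSE,
         fit_window = window, message = msg),
    class = "sigmoid_fit")

  s0 <- unname(quantile(y, 0.95))
  if (s0 <= 0) return(failed("non-positive tension plateau"))
  cross <- function(level) {
    i <- which(y >= level)[1]
    if (is.na(i)) NA_real_ else t[max(i, 1L)]
  }
  m0 <- cross(s0 / 2); t10 <- cross(0.1 * s0); t90 <- cross(0.9 * s0)
  b0 <- if (is.na(t10) || is.na(t90) || t90 <= t10) 0.5 else 4 / (t90 - t10)
  if (is.na(m0)) m0 <- median(t)
  starts <- list(list(S = s0, b = min(b0, 100), m = m0),
                 list(S = max(y), b = 0.5, m = median(t)))
  upper_S <- 10 * max(y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ S / (1 + exp(-b * (t - m))),
                        start = st,
                        lower = c(S = 1e-9, b = 1e-9, m = -Inf),
                        upper = c(S = upper_S, b = 100, m = Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = max_iter)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      co <- coef(fit)
      return(structure(
        list(S_d = unname(co["S"]), a = 1, b = unname(co["b"]),
             c = unname(co["m"]), rss = sum(resid(fit)^2),
             n_points = length(idx), converged = TRUE, fit_window = window,
             message = "converged"),
        class = "sigmoid_fit"))
    }
  }
  failed(conditionMessage(fit))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<sigmoid_fit> S_d = %.3f N/m, b = %.3f 1/s, half-max at %.2f s (rss %.3g, n %d)\n",
      x$S_d, x$b, x$c, x$rss, x$n_points))
  else
    cat(sprintf("<sigmoid_fit> not converged: %s\n", x$message))
  invisible(x)
}

#' Delamination strength of one peel record
#'
#' Full single-sample analysis: width-normalize the force trace to peel
#' tension, truncate at the terminal failure drop, and fit the sigmoid
#' plateau model. The returned `S_d` is the delamination strength in N/m.
#'
#' @param record a [peel_record()].
#' @param drop_fraction,min_level_frac see [truncate_at_failure()].
#' @param ... passed to [fit_sigmoid()].
#' @return a `sigmoid_fit` (see [fit_sigmoid()]).
#' @examples
#' tr <- gen_peel_trace(peel_trace_params(S_d_true = 20, noise_sd = 0))
#' delamination_strength(tr$record)$S_d
#' @export
delamination_strength <- function(record, drop_fraction = 0.5,
                                  min_level_frac = 0.6, ...) {
  tension <- peel_tension(record)
  window <- truncate_at_failure(tension, drop_fraction, min_level_frac)
  fit_sigmoid(record$time, tension, window, ...)
}
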