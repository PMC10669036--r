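#' Parameters for a synthetic peel-test trace
#'
#' Bundles the ground truth of one simulated T-peel experiment: the sigmoid
#' parameters of the tension curve, the sample geometry, the recording
#' settings and the failure time at which the specimen tears apart.
#'
#' The noiseless tension follows
#' \eqn{T_p(t) = S_d / (1 + a e^{-b (t - c)})} before `fail_time`; the
#' recorded force is `width * T_p(t)` plus additive Gaussian sensor noise.
#' After `fail_time` the force drops exponentially toward zero with a time
#' constant of one second, mimicking the sudden terminal failure seen on real
#' traces; the exact drop shape is irrelevant downstream because fitting
#' truncates at failure.
#'
#' @param S_d_true plateau tension (delamination strength), N/m.
#' @param a_true,b_true,c_true sigmoid shape parameters (dimensionless, 1/s,
#'   s). `a_true` and `c_true` jointly fix the half-maximum time
#'   `c_true + log(a_true) / b_true`.
#' @param width sample width in meters (the five recorded width measurements
#'   are all set to this value).
#' @param duration recording length, s.
#' @param sample_rate load-cell sampling rate, Hz. The recording hardware's
#'   actual rate is not critical on second-scale traces; 10 Hz default.
#' @param noise_sd additive force-noise standard deviation, N.
#' @param fail_time onset of the terminal failure drop, s; must lie in
#'   `(0, duration]`.
#' @param seed optional integer seed making the generated trace reproducible.
#' @return a `peel_trace_params` list.
#' @seealso [gen_peel_trace()]
#' @export
peel_trace_params <- function(S_d_true = 20, a_true = 50, b_true = 0.5,
                              c_true = 10, width = 3e-3, duration = 80,
                              sample_rate = 10, noise_sd = 0.003,
                              fail_time = 70, seed = NULL) {
  check_number(S_d_true, "S_d_true", positive = TRUE)
  check_number(a_true, "a_true", positive = TRUE)
  check_number(b_true, "b_true", positive = TRUE)
  check_number(c_true, "c_true")
  check_number(width, "width", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_number(sample_rate, "sample_rate", positive = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(fail_time, "fail_time")
  if (fail_time <= 0 || fail_time > duration)
    stop("`fail_time` must satisfy 0 < fail_time <= duration", call. = FALSE)
  structure(list(S_d_true = S_d_true, a_true = a_true, b_true = b_true,
                 c_true = c_true, width = width, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 fail_time = fail_time, seed = seed),
            class = "peel_trace_params")
}

#' A peel-test record
#'
#' One specimen's force--time trace together with its geometry and grouping
#' metadata. Times must be strictly increasing and all width measurements
#' positive (five measurements along the sample are expected, but any
#' non-empty set is accepted).
#'
#' @param time seconds, strictly increasing.
#' @param force newtons, same length as `time`.
#' @param widths width measurements in meters.
#' @param group,direction,rat_id,sample_id metadata labels.
#' @return a `peel_record` list.
#' @export
peel_record <- function(time, force, widths, group = NA_character_,
                        direction = NA_character_, rat_id = NA_character_,
                        sample_id = NA_character_) {
  if (length(time) != length(force))
    stop("`time` and `force` must have the same length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(force)))
    stop("`force` must be finite", call. = FALSE)
  if (length(widths) < 1 || !all(is.finite(widths)) || any(widths <= 0))
    stop("`widths` must be a non-empty vector of positive numbers",
         call. = FALSE)
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 widths = as.numeric(widths), group = group,
                 direction = direction, rat_id = rat_id,
                 sample_id = sample_id),
            class = "peel_record")
}

#' @export
print.peel_record <- function(x, ...) {
  cat(sprintf("<peel_record> %s  %d points, %.1f s, width %.2f mm (%s/%s/%s)\n",
              x$sample_id, length(x$time), max(x$time),
              mean(x$widths) * 1e3, x$group, x$direction, x$rat_id))
  invisible(x)
}

#' The sigmoid peel-tension model
#'
#' \eqn{T_p(t) = S_d / (1 + a e^{-b (t - c)})}. Note that `a` and `c` enter
#' only through the combination `a * exp(b * c)`: the curve is fully
#' determined by `S_d`, `b` and the half-maximum time
#' `m = c + log(a) / b`.
#'
#' @param t time, s.
#' @param S_d plateau, N/m.
#' @param a,b,c shape parameters.
#' @return tension, N/m.
#' @export
sigmoid_tension <- function(t, S_d, a, b, c) {
  S_d / (1 + a * exp(-b * (t - c)))
}

#' Generate a synthetic peel-test trace
#'
#' Simulates a load-cell recording of a T-peel test: sigmoid rise to the
#' plateau `width * S_d_true`, additive Gaussian noise, and an exponential
#' terminal drop after `fail_time` (time constant 1 s).
#'
#' @param params a [peel_trace_params()] object.
#' @param ... metadata (`group`, `direction`, `rat_id`, `sample_id`) passed
#'   to [peel_record()].
#' @return a list with `record` (a [peel_record()]) and `truth`, the
#'   generating parameters including the identifiable half-maximum time
#'   `m_true = c_true + log(a_true) / b_true`.
#' @examples
#' tr <- gen_peel_trace(peel_trace_params(noise_sd = 0, seed = 1))
#' max(tr$record$force) / mean(tr$record$widths) # ~ S_d_true
#' @export
gen_peel_trace <- function(params = peel_trace_params(), ...) {
  stopifnot(inherits(params, "peel_trace_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t <- seq(0, params$duration, by = 1 / params$sample_rate)
  clean <- params$width * sigmoid_tension(t, params$S_d_true, params$a_true,
                                          params$b_true, params$c_true)
  post <- t >= params$fail_time
  if (any(post)) {
    f_at_fail <- params$width *
      sigmoid_tension(params$fail_time, params$S_d_true, params$a_true,
                      params$b_true, params$c_true)
    clean[post] <- f_at_fail * exp(-(t[post] - params$fail_time))
  }
  force <- clean
  if (params$noise_sd > 0)
    force <- force + rnorm(length(t), 0, params$noise_sd)
  truth <- params[c("S_d_true", "a_true", "b_true", "c_true", "width",
                    "fail_time")]
  truth$m_true <- params$c_true + log(params$a_true) / params$b_true
  list(record = peel_record(t, force, rep(params$width, 5), ...),
       truth = truth)
}
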