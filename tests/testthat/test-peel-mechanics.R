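test_that("mean_width averages and validates", {
  expect_equal(mean_width(rep(3e-3, 5)), 3e-3)
  expect_equal(mean_width(c(2.8, 3.0, 3.2, 3.0, 3.0) * 1e-3), 3e-3)
  expect_equal(mean_width(4e-3), 4e-3)
  expect_error(mean_width(numeric()), "non-empty")
  expect_error(mean_width(c(3e-3, -1e-3)), "positive")
})

test_that("peel tension is force over mean width, elementwise", {
  rec <- peel_record(0:9, rep(0.06, 10), rep(3e-3, 5))
  expect_equal(peel_tension(rec), rep(20, 10))
  rec0 <- peel_record(0:9, rep(0, 10), rep(3e-3, 5))
  expect_equal(peel_tension(rec0), rep(0, 10))
  # doubling widths halves tension
  rec2 <- peel_record(0:9, rep(0.06, 10), rep(6e-3, 5))
  expect_equal(peel_tension(rec2), peel_tension(rec) / 2)
})

test_that("failure truncation finds the drop and keeps rising traces whole", {
  expect_equal(truncate_at_failure(1:20)[["end"]], 20L)
  stepped <- c(seq(1, 20, length.out = 30), rep(20, 30), rep(2, 10))
  w <- truncate_at_failure(stepped, drop_fraction = 0.5)
  expect_equal(w[["end"]], 60L)
  expect_error(truncate_at_failure(1:5), "at least 10")
  expect_error(truncate_at_failure(1:20, drop_fraction = 1.2), "0, 1")
})

test_that("truncation lands near the true failure time on synthetic traces", {
  # brute-force check: window end must sit within 2 s of the failure onset
  for (seed in 1:5) {
    p <- peel_trace_params(fail_time = 60, noise_sd = 0.002, seed = seed)
    tr <- gen_peel_trace(p)
    w <- truncate_at_failure(peel_tension(tr$record))
    expect_lt(abs(tr$record$time[w[["end"]]] - 60), 2)
  }
})

test_that("sigmoid fitting recovers the identifiable parameters exactly", {
  # the model's (a, c) pair is identifiable only through the half-maximum
  # time m = c + log(a)/b; the fit reports the canonical a = 1, c = m
  t <- seq(0, 60, 0.1)
  y <- sigmoid_tension(t, 20, 50, 0.5, 10)
  fit <- fit_sigmoid(t, y)
  m_true <- 10 + log(50) / 0.5
  expect_true(fit$converged)
  expect_lt(abs(fit$S_d - 20) / 20, 1e-6)
  expect_lt(abs(fit$b - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$c - m_true) / m_true, 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("time translation shifts c and leaves S_d and b unchanged", {
  t <- seq(0, 60, 0.1)
  y <- sigmoid_tension(t, 20, 50, 0.5, 10)
  f0 <- fit_sigmoid(t, y)
  f5 <- fit_sigmoid(t + 5, y)
  expect_equal(f5$S_d, f0$S_d, tolerance = 1e-8)
  expect_equal(f5$b, f0$b, tolerance = 1e-8)
  expect_equal(f5$c, f0$c + 5, tolerance = 1e-6)
})

test_that("fitted curve is monotone with supremum S_d", {
  t <- seq(0, 80, 0.1)
  set.seed(2)
  y <- sigmoid_tension(t, 18, 40, 0.4, 12) + rnorm(length(t), 0, 0.5)
  fit <- fit_sigmoid(t, y)
  curve <- sigmoid_tension(t, fit$S_d, fit$a, fit$b, fit$c)
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve <= fit$S_d))
})

test_that("degenerate fit inputs are rejected or flagged, never imputed", {
  expect_error(fit_sigmoid(1:4, c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_sigmoid(1:10, rep(1, 10), window = c(1, 20)), "bounds")
  flat <- fit_sigmoid(seq(0, 10, 0.1), rep(0, 101))
  expect_false(flat$converged)
  expect_true(is.na(flat$S_d))
})

test_that("full pipeline recovers noiseless strength and scales linearly", {
  p <- peel_trace_params(S_d_true = 20, noise_sd = 0)
  tr <- gen_peel_trace(p)
  fit <- delamination_strength(tr$record)
  expect_equal(fit$S_d, 20, tolerance = 0.01 / 20)
  # doubling the force doubles S_d
  rec2 <- peel_record(tr$record$time, tr$record$force * 2,
                      tr$record$widths)
  expect_equal(delamination_strength(rec2)$S_d, 2 * fit$S_d,
               tolerance = 1e-8)
  # doubling the width halves S_d
  rec3 <- peel_record(tr$record$time, tr$record$force,
                      tr$record$widths * 2)
  expect_equal(delamination_strength(rec3)$S_d, fit$S_d / 2,
               tolerance = 1e-8)
})

test_that("control-like and dissection-like batches separate correctly", {
  set.seed(31)
  fit_batch <- function(S, n) replicate(n, {
    p <- peel_trace_params(S_d_true = rnorm(1, S, 0.1 * S),
                           noise_sd = 0.003)
    delamination_strength(gen_peel_trace(p)$record)$S_d
  })
  ctrl <- fit_batch(20, 20)
  diss <- fit_batch(11, 14)
  expect_gt(mean(ctrl), mean(diss))
  expect_gt(mean(ctrl) - mean(diss), 5)
})
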