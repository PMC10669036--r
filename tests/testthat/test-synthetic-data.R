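test_that("noiseless traces follow the sigmoid model exactly before failure", {
  for (par in list(list(S = 20, a = 50, b = 0.5, cc = 10),
                   list(S = 11, a = 20, b = 0.8, cc = 5),
                   list(S = 35, a = 120, b = 0.3, cc = 15))) {
    p <- peel_trace_params(S_d_true = par$S, a_true = par$a, b_true = par$b,
                           c_true = par$cc, noise_sd = 0, fail_time = 60)
    tr <- gen_peel_trace(p)
    pre <- tr$record$time < 60
    expected <- p$width * sigmoid_tension(tr$record$time[pre], par$S, par$a,
                                          par$b, par$cc)
    expect_lt(max(abs(tr$record$force[pre] - expected) / expected[expected > 0]),
              1e-12)
  }
})

test_that("trace values match hand algebra at the asymptote and at t = c", {
  p <- peel_trace_params(S_d_true = 20, a_true = 50, b_true = 0.5,
                         c_true = 10, width = 3e-3, noise_sd = 0,
                         duration = 200, fail_time = 200)
  tr <- gen_peel_trace(p)
  tension <- tr$record$force / p$width
  # late plateau approaches S_d_true
  expect_equal(tension[length(tension)], 20, tolerance = 1e-6)
  # at t = c the sigmoid sits at S_d / (1 + a)
  i <- which(tr$record$time == 10)
  expect_equal(tension[i], 20 / (1 + 50), tolerance = 1e-12)
  # plateau force for 20 N/m x 3 mm is about 0.06 N
  expect_equal(max(tr$record$force), 0.06, tolerance = 1e-3)
})

test_that("trace generation fails loudly on invalid parameters", {
  expect_error(peel_trace_params(S_d_true = -1), "S_d_true")
  expect_error(peel_trace_params(b_true = 0), "b_true")
  expect_error(peel_trace_params(fail_time = 100, duration = 80),
               "fail_time")
  expect_error(peel_trace_params(sample_rate = 0), "sample_rate")
})

test_that("synthetic histology truth is a disjoint partition of the ROI", {
  img <- gen_histology_image(histo_image_params(seed = 3,
                                                color_noise_sd = 5))
  m <- img$truth$masks
  # pairwise disjoint
  nm <- names(m)
  for (i in seq_along(m)) for (j in seq_along(m)) {
    if (i < j) expect_equal(sum(m[[i]] & m[[j]]), 0,
                            info = paste(nm[i], nm[j]))
  }
  # union covers the ROI
  covered <- Reduce(`|`, m)
  expect_true(all(covered[img$roi]))
  # fractions sum to 1
  expect_equal(sum(img$truth$fractions), 1, tolerance = 1e-9)
  # fiber truth equals fiber mask area over ROI area
  expect_equal(img$truth$lambda_fibers, sum(m$fibers) / sum(img$roi))
})

test_that("zero fibers and noiseless colors behave as constructed", {
  p <- histo_image_params(fiber_fraction = NULL, fiber_count = 0,
                          color_noise_sd = 0, seed = 4)
  img <- gen_histology_image(p)
  expect_equal(img$truth$lambda_fibers, 0)
  # noiseless separable palette: classification against the palette itself
  # reproduces the truth fractions exactly
  lm <- classify_pixels(img$image, p$palette, img$roi)
  expect_equal(unname(area_fractions(lm)$fractions),
               unname(img$truth$fractions))
})

test_that("impossible area targets raise a generation error", {
  expect_error(
    gen_histology_image(histo_image_params(
      target_fractions = c(collagen = 0.9, background = 0.1), seed = 1)),
    "exceed available area")
})

test_that("study generation is deterministic and labels groups", {
  spec <- default_study_spec()
  for (n in names(spec)) { spec[[n]]$n_rats <- 2L; spec[[n]]$n_histo <- 2L }
  a <- gen_group_dataset(spec, seed = 9, materialize = FALSE)$samples
  b <- gen_group_dataset(spec, seed = 9, materialize = FALSE)$samples
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(unique(a$group),
                  c("Control", "Pre-dissection", "Dissection"))
  expect_setequal(unique(a$direction), c("theta", "z"))
  expect_true(all(table(a$group, a$direction) == 4))
})

test_that("a group with zero rats yields an empty group, not an error", {
  spec <- list(a = group_spec("a", n_rats = 2, samples_per_rat = 1,
                              n_histo = 0),
               b = group_spec("b", n_rats = 0, samples_per_rat = 1,
                              n_histo = 0))
  s <- gen_group_dataset(spec, seed = 1, materialize = FALSE)$samples
  expect_equal(sum(s$group == "b"), 0)
  expect_equal(sum(s$group == "a"), 4) # 2 rats x 1 sample x 2 directions
})

test_that("generated group means preserve the designed strength ordering", {
  spec <- default_study_spec()
  for (n in names(spec)) spec[[n]]$n_histo <- 0L
  ds <- gen_group_dataset(spec, seed = 21, materialize = FALSE)
  m <- tapply(ds$samples$S_d_true, ds$samples$group, mean)
  expect_gt(m[["Control"]], m[["Pre-dissection"]])
  expect_gt(m[["Pre-dissection"]], m[["Dissection"]])
})
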