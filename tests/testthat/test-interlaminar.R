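test_that("elastin thresholding selects low-green pixels within the ROI", {
  # all-white image: nothing below any threshold < 255
  white <- array(255, dim = c(8, 8, 3))
  expect_equal(sum(elastin_mask(white, threshold = 200)), 0)
  # noiseless synthetic: mask equals lamina + fiber truth exactly
  p <- histo_image_params(color_noise_sd = 0, seed = 11)
  img <- gen_histology_image(p)
  m <- elastin_mask(img$image, img$roi, threshold = 120,
                    px_size = img$px_size)
  truth <- img$truth$masks$lamina | img$truth$masks$fibers
  expect_identical(unname(m[, ]), truth)
  # automatic threshold lands between the elastin and tissue green modes
  m_auto <- elastin_mask(img$image, img$roi, px_size = img$px_size)
  expect_gt(attr(m_auto, "threshold"), 60)
  expect_lt(attr(m_auto, "threshold"), 180)
  expect_identical(unname(m_auto[, ]), truth)
  expect_error(elastin_mask(img$image, threshold = 300), "255")
})

test_that("erosion and dilation follow 3x3 square morphology", {
  m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE
  expect_identical(mask_erode(m, 0), m)
  e1 <- mask_erode(m, 1)
  expect_equal(which(e1), which(matrix(seq_len(81), 9, 9) == 41))
  expect_equal(sum(mask_erode(m, 2)), 0)
  d1 <- mask_dilate(e1, 1)
  expect_identical(d1, m)
  expect_error(mask_erode(m, -1), "non-negative")
})

test_that("opening is anti-extensive and idempotent", {
  set.seed(12)
  for (i in 1:10) {
    m <- random_mask()
    o <- mask_open(m, 2)
    expect_true(all(o <= m))           # opening never adds pixels
    expect_identical(mask_open(o, 2), o) # idempotent at the same radius
  }
})

test_that("particle features match hand geometry", {
  # single pixel: area = px^2, circularity defined as 1
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  r <- label_regions(single, px_size = 0.25)
  expect_equal(r$area, 0.0625)
  expect_equal(r$circularity, 1)
  # 1 x 100 line: traced perimeter 2(L-1), strongly elongated
  line <- matrix(FALSE, 5, 104); line[3, 3:102] <- TRUE
  rl <- label_regions(line, px_size = 0.25)
  expect_equal(rl$pixel_count, 100L)
  expect_equal(rl$perimeter, 2 * 99 * 0.25)
  expect_lt(rl$circularity, 0.3)
  # rasterized disk: circularity near 1
  rd <- label_regions(disk_mask(30), px_size = 1)
  expect_gt(rd$circularity, 0.85)
  # empty mask: zero rows
  expect_equal(nrow(label_regions(matrix(FALSE, 4, 4))), 0)
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE # diagonal chain
  r <- label_regions(m)
  expect_equal(nrow(r), 1)
  expect_equal(r$pixel_count, 3L)
})

test_that("EL selection keeps laminas and rejects compact blobs", {
  # a disk is compact: fails the circularity window, EL mask empty
  d <- disk_mask(20)
  attr(d, "px_size") <- 0.25
  expect_equal(sum(el_mask(d)), 0)
  # empty input stays empty
  expect_equal(sum(el_mask(matrix(FALSE, 20, 20), px_size = 0.25)), 0)
  # laminas-only image: EL mask recovers the opened laminas (Dice >= 0.9)
  p <- histo_image_params(fiber_fraction = NULL, fiber_count = 0,
                          color_noise_sd = 0, seed = 13)
  img <- gen_histology_image(p)
  ela <- elastin_mask(img$image, img$roi, threshold = 120,
                      px_size = img$px_size)
  el <- el_mask(ela)
  lam <- img$truth$masks$lamina
  dice <- 2 * sum(el & lam) / (sum(el) + sum(lam))
  expect_gt(dice, 0.9)
})

test_that("mask subtraction is set difference", {
  set.seed(14)
  a <- random_mask(); b <- random_mask()
  expect_equal(sum(subtract_masks(a, a)), 0)
  expect_identical(subtract_masks(a, matrix(FALSE, nrow(a), ncol(a))), a)
  r <- subtract_masks(a, b)
  expect_true(all(!(r & b)))   # disjoint from b
  expect_true(all(r <= a))     # contained in a
  expect_error(subtract_masks(a, matrix(FALSE, 2, 2)), "shape")
})

test_that("interlaminar fraction is a proportion of the media", {
  med <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(interlaminar_fraction(none, med), 0)
  expect_equal(interlaminar_fraction(med, med), 1)
  expect_error(interlaminar_fraction(none, none), "empty")
})

test_that("full extraction recovers known fiber fractions", {
  errs <- c()
  for (seed in 1:6) {
    p <- histo_image_params(fiber_fraction = 0.10, color_noise_sd = 8,
                            seed = seed)
    img <- gen_histology_image(p)
    ext <- extract_interlaminar(img$image, img$roi, img$px_size)
    errs <- c(errs, ext$lambda_fibers - img$truth$lambda_fibers)
    # structural invariants of the mask chain
    expect_true(all(ext$el <= ext$elastin))
    expect_true(all(ext$fibers <= ext$elastin))
    expect_equal(sum(ext$fibers & ext$el), 0)
    expect_lte(ext$lambda_fibers, mean(ext$elastin))
  }
  expect_lt(max(abs(errs)), 0.03)
})
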