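#' Default stain palettes
#'
#' RGB centroids (0--255) used to paint synthetic stained sections. The
#' Elastica--Masson palette shows elastin dark purple, collagen light blue,
#' smooth muscle pink and background white; the Azan palette shows collagen
#' blue, elastin pink, smooth muscle red and background white. Exact values
#' are configuration, not ground truth: the generator records which pixels
#' belong to which component before color noise is added. Colors are chosen
#' well separated (minimum pairwise distance > 100 in RGB space) and with a
#' markedly lower green channel for elastin under Elastica--Masson, matching
#' how elastin is thresholded.
#'
#' @return a 4 x 3 numeric matrix with rows `elastin`, `collagen`,
#'   `smooth_muscle`, `background` and columns `r`, `g`, `b`.
#' @export
em_palette <- function() {
  m <- rbind(elastin       = c(80, 45, 110),
             collagen      = c(140, 190, 225),
             smooth_muscle = c(225, 140, 170),
             background    = c(250, 250, 250))
  colnames(m) <- c("r", "g", "b")
  m
}

#' @rdname em_palette
#' @export
azan_palette <- function() {
  m <- rbind(elastin       = c(235, 150, 170),
             collagen      = c(60, 90, 200),
             smooth_muscle = c(200, 60, 70),
             background    = c(250, 248, 242))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Parameters for a synthetic stained-section image
#'
#' Describes a layered arterial-media look-alike: `n_laminas` roughly
#' horizontal, sinusoidally wavy elastin bands (the elastic laminas), small
#' elongated elastin specks between them (the interlaminar fibers, biased
#' toward the radial/row direction), and the remaining area tiled with
#' collagen / smooth-muscle / background blobs. All geometric sizes are in
#' micrometers and converted through `px_size`.
#'
#' @param height,width image size in pixels.
#' @param px_size micrometers per pixel.
#' @param n_laminas number of elastic laminas.
#' @param lamina_thickness lamina band thickness, um. Must comfortably
#'   survive the five-iteration binary opening used downstream
#'   (> 11 px, i.e. > `11 * px_size` um).
#' @param lamina_waviness sinusoid amplitude of the lamina centerline, um.
#' @param lamina_wavelength sinusoid wavelength, um.
#' @param fiber_fraction target area fraction of interlaminar fibers over the
#'   ROI; fibers are placed until this is reached. Set `NULL` to place
#'   exactly `fiber_count` fibers instead.
#' @param fiber_count number of fibers when `fiber_fraction` is `NULL`.
#' @param fiber_length_range fiber length range, um.
#' @param fiber_width fiber width, um.
#' @param fiber_angle_sd SD (radians) of the fiber angle around the radial
#'   (row) direction.
#' @param palette 4 x 3 RGB centroid matrix, rows `elastin`, `collagen`,
#'   `smooth_muscle`, `background` (see [em_palette()]).
#' @param color_noise_sd per-channel Gaussian color noise SD.
#' @param target_fractions named vector with entries `collagen` and
#'   `background`: intended area fractions *of the whole ROI* for those
#'   components; smooth muscle takes whatever area remains after laminas and
#'   fibers.
#' @param seed optional integer seed.
#' @return a `histo_image_params` list.
#' @seealso [gen_histology_image()]
#' @export
histo_image_params <- function(height = 150, width = 200, px_size = 0.25,
                               n_laminas = 4, lamina_thickness = 4,
                               lamina_waviness = 1, lamina_wavelength = 30,
                               fiber_fraction = 0.10, fiber_count = 60,
                               fiber_length_range = c(1.5, 3.5),
                               fiber_width = 0.75, fiber_angle_sd = 0.3,
                               palette = em_palette(), color_noise_sd = 0,
                               target_fractions = c(collagen = 0.125,
                                                    background = 0.05),
                               seed = NULL) {
  check_number(height, "height", positive = TRUE)
  check_number(width, "width", positive = TRUE)
  check_number(px_size, "px_size", positive = TRUE)
  check_number(n_laminas, "n_laminas", min = 0)
  check_number(lamina_thickness, "lamina_thickness", positive = TRUE)
  check_number(lamina_waviness, "lamina_waviness", min = 0)
  check_number(lamina_wavelength, "lamina_wavelength", positive = TRUE)
  if (!is.null(fiber_fraction))
    check_number(fiber_fraction, "fiber_fraction", min = 0, max = 1)
  check_number(fiber_count, "fiber_count", min = 0)
  check_number(fiber_width, "fiber_width", positive = TRUE)
  check_number(fiber_angle_sd, "fiber_angle_sd", min = 0)
  check_number(color_noise_sd, "color_noise_sd", min = 0)
  comp <- c("elastin", "collagen", "smooth_muscle", "background")
  if (!is.matrix(palette) || !all(comp %in% rownames(palette)))
    stop("`palette` must be a matrix with rows elastin, collagen, ",
         "smooth_muscle, background", call. = FALSE)
  if (any(palette < 0) || any(palette > 255))
    stop("`palette` channels must be in [0, 255]", call. = FALSE)
  if (!all(c("collagen", "background") %in% names(target_fractions)))
    stop("`target_fractions` needs named entries `collagen` and `background`",
         call. = FALSE)
  if (any(target_fractions < 0) || any(target_fractions > 1))
    stop("`target_fractions` must be in [0, 1]", call. = FALSE)
  if (length(fiber_length_range) != 2 || any(fiber_length_range <= 0) ||
      fiber_length_range[1] > fiber_length_range[2])
    stop("`fiber_length_range` must be an increasing pair of positive ",
         "lengths", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 px_size = px_size, n_laminas = as.integer(n_laminas),
                 lamina_thickness = lamina_thickness,
                 lamina_waviness = lamina_waviness,
                 lamina_wavelength = lamina_wavelength,
                 fiber_fraction = fiber_fraction,
                 fiber_count = as.integer(fiber_count),
                 fiber_length_range = fiber_length_range,
                 fiber_width = fiber_width, fiber_angle_sd = fiber_angle_sd,
                 palette = palette[comp, , drop = FALSE],
                 color_noise_sd = color_noise_sd,
                 target_fractions = target_fractions, seed = seed),
            class = "histo_image_params")
}

# rasterize one fiber bar; returns an index matrix (row, col), deduplicated
rasterize_bar <- function(cy, cx, length_px, width_px, theta, h, w) {
  s <- seq(-length_px / 2, length_px / 2, by = 0.4)
  o <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 0.4)
  g <- expand.grid(s = s, o = o)
  rr <- round(cy + g$s * cos(theta) - g$o * sin(theta))
  cc <- round(cx + g$s * sin(theta) + g$o * cos(theta))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  unique(cbind(rr[ok], cc[ok]))
}

# smooth random scalar field used to tile the non-elastin remainder into
# contiguous collagen / smooth-muscle / background blobs
random_blob_field <- function(h, w, n_waves = 4) {
  f <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_waves)) {
    kx <- runif(1, 0.5, 2.5) * 2 * pi / w
    ky <- runif(1, 0.5, 2.5) * 2 * pi / h
    f <- f + runif(1, 0.5, 1) * sin(kx * cols + runif(1, 0, 2 * pi)) *
      sin(ky * rows + runif(1, 0, 2 * pi))
  }
  f + matrix(rnorm(h * w, 0, 0.05), h, w) # break ties between equal cells
}

#' Generate a synthetic stained-section image with ground truth
#'
#' Paints elastic laminas (wavy horizontal bands) and interlaminar fibers
#' (short bars biased toward the radial direction) with the elastin palette
#' color, tiles the remaining ROI with collagen / smooth-muscle / background
#' blobs according to `target_fractions`, then adds per-channel Gaussian
#' color noise. Truth masks are recorded before the noise, so every
#' downstream estimate can be scored exactly.
#'
#' @param params a [histo_image_params()] object.
#' @return a list:
#' \describe{
#'   \item{image}{`height x width x 3` array, 0--255.}
#'   \item{roi}{logical media mask (here the full frame).}
#'   \item{truth}{list with `masks` (pairwise-disjoint logical matrices
#'     `lamina`, `fibers`, `collagen`, `smooth_muscle`, `background`),
#'     `fractions` (named, elastin = laminas + fibers; sums to 1) and
#'     `lambda_fibers` (fiber area / ROI area).}
#'   \item{px_size}{micrometers per pixel.}
#' }
#' @examples
#' img <- gen_histology_image(histo_image_params(seed = 1))
#' img$truth$fractions
#' @export
gen_histology_image <- function(params = histo_image_params()) {
  stopifnot(inherits(params, "histo_image_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  h <- params$height; w <- params$width; px <- params$px_size
  roi <- matrix(TRUE, h, w)
  n_roi <- h * w

  # elastic laminas: wavy horizontal bands
  lamina <- matrix(FALSE, h, w)
  t_px <- params$lamina_thickness / px
  amp_px <- params$lamina_waviness / px
  wl_px <- params$lamina_wavelength / px
  if (params$n_laminas > 0) {
    centers <- (seq_len(params$n_laminas) - 0.5) * h / params$n_laminas
    xx <- seq_len(w)
    for (i in seq_len(params$n_laminas)) {
      cy <- centers[i] + amp_px * sin(2 * pi * xx / wl_px + runif(1, 0, 2 * pi))
      r0 <- pmax(1L, ceiling(cy - t_px / 2))
      r1 <- pmin(h, floor(cy + t_px / 2))
      for (x in xx) if (r1[x] >= r0[x]) lamina[r0[x]:r1[x], x] <- TRUE
    }
  }

  # interlaminar fibers: short near-radial bars, never on a lamina
  fibers <- matrix(FALSE, h, w)
  len_px <- params$fiber_length_range / px
  wid_px <- max(1, params$fiber_width / px)
  need <- if (is.null(params$fiber_fraction)) Inf else
    round(params$fiber_fraction * n_roi)
  placed <- 0L
  max_tries <- 50 * max(params$fiber_count, need / 10, 1)
  tries <- 0
  while (tries < max_tries) {
    tries <- tries + 1
    if (is.null(params$fiber_fraction)) {
      if (placed >= params$fiber_count) break
    } else if (sum(fibers) >= need) break
    L <- runif(1, len_px[1], len_px[2])
    idx <- rasterize_bar(runif(1, 2, h - 1), runif(1, 2, w - 1), L, wid_px,
                         rnorm(1, 0, params$fiber_angle_sd), h, w)
    idx <- idx[!lamina[idx], , drop = FALSE]
    if (nrow(idx) < 0.4 * L * wid_px) next # mostly clipped by a lamina
    fibers[idx] <- TRUE
    placed <- placed + 1L
  }
  if (!is.null(params$fiber_fraction) && sum(fibers) < need * 0.95)
    stop("could not reach the requested `fiber_fraction`; ",
         "target fractions exceed available area", call. = FALSE)

  # tile the remainder with collagen / smooth muscle / background blobs
  elastin <- lamina | fibers
  rest_idx <- which(!elastin)
  n_col <- round(params$target_fractions[["collagen"]] * n_roi)
  n_bg <- round(params$target_fractions[["background"]] * n_roi)
  if (n_col + n_bg > length(rest_idx))
    stop("target fractions exceed available area: collagen + background ",
         "targets leave no room for smooth muscle", call. = FALSE)
  field <- random_blob_field(h, w)
  ord <- rest_idx[order(field[rest_idx])]
  collagen <- matrix(FALSE, h, w); collagen[ord[seq_len(n_col)]] <- TRUE
  background <- matrix(FALSE, h, w)
  if (n_bg > 0) background[ord[n_col + seq_len(n_bg)]] <- TRUE
  smooth_muscle <- !elastin & !collagen & !background

  # paint and add color noise
  pal <- params$palette
  img <- array(0, dim = c(h, w, 3))
  comp_masks <- list(elastin = elastin, collagen = collagen,
                     smooth_muscle = smooth_muscle, background = background)
  for (comp in names(comp_masks))
    for (ch in 1:3)
      img[, , ch][comp_masks[[comp]]] <- pal[comp, ch]
  if (params$color_noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, params$color_noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 255] <- 255
  }

  fractions <- vapply(comp_masks, function(m) sum(m) / n_roi, numeric(1))
  list(image = img, roi = roi,
       truth = list(masks = list(lamina = lamina, fibers = fibers,
                                 collagen = collagen,
                                 smooth_muscle = smooth_muscle,
                                 background = background),
                    fractions = fractions,
                    lambda_fibers = sum(fibers) / n_roi),
       px_size = px)
}
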