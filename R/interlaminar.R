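#' Otsu threshold of a sample of channel values
#'
#' Bimodal histogram split maximizing between-class variance on 0--255
#' integer-binned values. Implemented in-package so it can be computed from
#' the ROI pixel subset alone.
#'
#' @param values numeric vector of channel values in [0, 255].
#' @return threshold level `T` (numeric); `values < T` is the lower class.
#' @keywords internal
otsu_threshold <- function(values) {
  v <- pmin(255L, pmax(0L, as.integer(round(values))))
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  # on cleanly separated modes the criterion is flat between them: take the
  # midpoint of the maximal plateau, not its first level
  top <- which(sb >= max(sb) * (1 - 1e-12))
  mean(range(top)) - 1 + 0.5
}

#' Elastin mask by green-channel thresholding
#'
#' In Elastica--Masson images elastin has a markedly smaller green value
#' than collagen, smooth muscle and background, so a pixel is called elastin
#' when its green channel lies strictly below the threshold. With
#' `threshold = NULL` the threshold is computed automatically from the
#' green-channel histogram of the ROI pixels (Otsu's bimodal split).
#'
#' @param image `h x w x 3` RGB array, 0--255.
#' @param roi logical media mask; default the whole frame.
#' @param threshold fixed green threshold in [0, 255], or `NULL` for
#'   automatic.
#' @param px_size micrometers per pixel, attached to the mask.
#' @return logical mask (`TRUE` = elastin, `FALSE` elsewhere and outside the
#'   ROI) with attributes `px_size` and `threshold`.
#' @export
elastin_mask <- function(image, roi = NULL, threshold = NULL,
                         px_size = 0.25) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  check_number(px_size, "px_size", positive = TRUE)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  check_mask(roi, "roi")
  check_same_shape(image, roi, "image", "roi")
  g <- image[, , 2]
  if (is.null(threshold)) {
    threshold <- otsu_threshold(g[roi])
  } else {
    check_number(threshold, "threshold", min = 0, max = 255)
  }
  mask <- g < threshold & roi
  attr(mask, "px_size") <- px_size
  attr(mask, "threshold") <- threshold
  mask
}

brush3 <- function() EBImage::makeBrush(3, shape = "box")

#' Iterated binary erosion and dilation
#'
#' 3 x 3 square structuring element, applied `iterations` times; zero
#' iterations is the identity. `mask_open()` is erosion followed by dilation
#' with the same iteration count, the operation used to suppress structures
#' thinner than about `2 * iterations + 1` pixels.
#'
#' @param mask logical matrix.
#' @param iterations non-negative integer.
#' @return logical matrix of the same shape (attributes preserved).
#' @export
mask_erode <- function(mask, iterations = 1) {
  check_mask(mask, "mask")
  if (length(iterations) != 1 || is.na(iterations) || iterations < 0)
    stop("`iterations` must be a non-negative integer", call. = FALSE)
  out <- mask * 1L
  b <- brush3()
  for (i in seq_len(iterations)) out <- EBImage::erode(out, b)
  res <- matrix(out > 0, nrow(mask), ncol(mask))
  attributes(res)[c("px_size")] <- attributes(mask)[c("px_size")]
  res
}

#' @rdname mask_erode
#' @export
mask_dilate <- function(mask, iterations = 1) {
  check_mask(mask, "mask")
  if (length(iterations) != 1 || is.na(iterations) || iterations < 0)
    stop("`iterations` must be a non-negative integer", call. = FALSE)
  out <- mask * 1L
  b <- brush3()
  for (i in seq_len(iterations)) out <- EBImage::dilate(out, b)
  res <- matrix(out > 0, nrow(mask), ncol(mask))
  attributes(res)[c("px_size")] <- attributes(mask)[c("px_size")]
  res
}

#' @rdname mask_erode
#' @export
mask_open <- function(mask, iterations = 1) {
  mask_dilate(mask_erode(mask, iterations), iterations)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass
label_8connected <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Particle analysis of a binary mask
#'
#' Finds 8-connected components and measures each as a particle: pixel
#' count, physical area (`pixel_count * px_size^2`), perimeter by tracing
#' the outer boundary with diagonal steps weighted sqrt(2), and circularity
#' `4 * pi * area / perimeter^2` clipped to at most 1 (discrete perimeter
#' estimates can push the raw value slightly above 1; degenerate particles
#' whose traced perimeter is zero, e.g. single pixels, are assigned
#' circularity 1).
#'
#' @param mask logical matrix.
#' @param px_size micrometers per pixel; defaults to the mask's `px_size`
#'   attribute, else 1.
#' @return a tibble with columns `label`, `pixel_count`, `area` (um^2),
#'   `perimeter` (um), `circularity`, plus the label matrix as attribute
#'   `labels`. Empty mask gives zero rows.
#' @export
label_regions <- function(mask, px_size = NULL) {
  check_mask(mask, "mask")
  if (is.null(px_size)) px_size <- attr(mask, "px_size")
  if (is.null(px_size)) px_size <- 1
  check_number(px_size, "px_size", positive = TRUE)
  lab <- label_8connected(mask)
  n <- max(lab)
  if (n == 0) {
    out <- tibble::tibble(label = integer(), pixel_count = integer(),
                          area = numeric(), perimeter = numeric(),
                          circularity = numeric())
    attr(out, "labels") <- lab
    return(out)
  }
  counts <- tabulate(lab[lab > 0], nbins = n)
  contours <- EBImage::ocontour(lab)
  perim_px <- vapply(seq_len(n), function(i) {
    pts <- contours[[as.character(i)]]
    if (is.null(pts)) pts <- contours[[i]]
    if (is.null(pts) || nrow(pts) < 2) return(0)
    d <- diff(rbind(pts, pts[1, , drop = FALSE]))
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  area <- counts * px_size^2
  perimeter <- perim_px * px_size
  circ <- ifelse(perimeter <= 0, 1,
                 pmin(1, 4 * pi * area / perimeter^2))
  out <- tibble::tibble(label = seq_len(n), pixel_count = counts,
                        area = area, perimeter = perimeter,
                        circularity = circ)
  attr(out, "labels") <- lab
  out
}

#' Elastic-lamina mask by opening and particle filtering
#'
#' Suppresses small elastin specks with a five-iteration binary opening
#' (erode x5 then dilate x5, 3 x 3 square element), then keeps only
#' particles that are both large enough (`min_area`, default 0.1 um^2) and
#' elongated (circularity within `circularity_range`, default 0--0.3). What
#' survives are the long thin elastic laminas; the area floor is tiny at
#' typical pixel sizes, so the circularity criterion dominates the
#' selection.
#'
#' @param elastin logical elastin mask (see [elastin_mask()]).
#' @param px_size micrometers per pixel; defaults to the mask's attribute.
#' @param min_area minimum particle area, um^2.
#' @param circularity_range inclusive `c(lo, hi)` circularity window.
#' @param iterations opening iteration count.
#' @return logical elastic-lamina mask (subset of the opened elastin mask).
#' @export
el_mask <- function(elastin, px_size = NULL, min_area = 0.1,
                    circularity_range = c(0, 0.3), iterations = 5) {
  check_mask(elastin, "elastin")
  if (is.null(px_size)) px_size <- attr(elastin, "px_size")
  if (is.null(px_size)) px_size <- 1
  opened <- mask_open(elastin, iterations)
  regions <- label_regions(opened, px_size)
  lab <- attr(regions, "labels")
  keep <- regions$label[regions$area >= min_area &
                          regions$circularity >= circularity_range[1] &
                          regions$circularity <= circularity_range[2]]
  res <- matrix(lab %in% keep, nrow(elastin), ncol(elastin))
  attr(res, "px_size") <- px_size
  res
}

#' Set difference of binary masks
#'
#' `a \ b`: pixels in `a` that are not in `b`. Used to isolate interlaminar
#' fibers as elastin minus elastic laminas.
#'
#' @param a,b logical matrices of the same shape.
#' @return logical matrix (`a & !b`), `a`'s attributes preserved.
#' @export
subtract_masks <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b")
  check_same_shape(a, b, "a", "b")
  res <- matrix(a & !b, nrow(a), ncol(a))
  attributes(res)[c("px_size")] <- attributes(a)[c("px_size")]
  res
}

#' Interlaminar-fiber area fraction
#'
#' Area of the fiber mask within the media divided by the media area,
#' dimensionless in [0, 1].
#'
#' @param fibers logical fiber mask.
#' @param media logical media (ROI) mask, non-empty.
#' @return lambda_fibers, a number in [0, 1].
#' @export
interlaminar_fraction <- function(fibers, media) {
  check_mask(fibers, "fibers"); check_mask(media, "media")
  check_same_shape(fibers, media, "fibers", "media")
  n <- sum(media)
  if (n == 0) stop("`media` mask is empty", call. = FALSE)
  sum(fibers & media) / n
}

#' Interlaminar fibers of one Elastica--Masson image
#'
#' The full extraction chain: green-channel elastin threshold, elastic
#' laminas by opening plus particle filtering, fibers by mask subtraction,
#' and the fiber area fraction of the media.
#'
#' @param image `h x w x 3` EM image, 0--255.
#' @param roi logical media mask; default the whole frame.
#' @param px_size micrometers per pixel.
#' @param threshold fixed green threshold or `NULL` for automatic.
#' @param min_area,circularity_range,iterations see [el_mask()].
#' @return list with `lambda_fibers`, `elastin`, `el`, `fibers` masks and
#'   the green `threshold` used.
#' @export
extract_interlaminar <- function(image, roi = NULL, px_size = 0.25,
                                 threshold = NULL, min_area = 0.1,
                                 circularity_range = c(0, 0.3),
                                 iterations = 5) {
  ela <- elastin_mask(image, roi, threshold, px_size)
  el <- el_mask(ela, px_size, min_area, circularity_range, iterations)
  fib <- subtract_masks(ela, el)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(ela), ncol(ela))
  list(lambda_fibers = interlaminar_fraction(fib, roi),
       elastin = ela, el = el, fibers = fib,
       threshold = attr(ela, "threshold"))
}
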