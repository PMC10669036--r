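#' Build a color reference from annotated points
#'
#' The RGB centroid of each tissue component is the per-channel arithmetic
#' mean of representative annotated pixels (30 per component in the standard
#' protocol). Annotations use 0-based pixel coordinates with `x` the column
#' and `y` the row, as exported by common image annotation tools.
#'
#' @param image `h x w x 3` RGB array, 0--255.
#' @param annotations data frame with columns `label`, `x`, `y`.
#' @return a `color_reference` list with `components` (ordered labels),
#'   `centroids` (k x 3 matrix) and `n_points`. Known tissue labels are
#'   ordered elastin, collagen, smooth_muscle, background; this order is the
#'   tie-break order in [classify_pixels()].
#' @export
build_color_reference <- function(image, annotations) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  need <- c("label", "x", "y")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("`annotations` must be a data frame with columns label, x, y",
         call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  xs <- annotations$x; ys <- annotations$y
  if (any(xs < 0 | xs >= w | ys < 0 | ys >= h))
    stop("annotation coordinates out of image bounds", call. = FALSE)
  canonical <- c("elastin", "collagen", "smooth_muscle", "background")
  labs <- unique(as.character(annotations$label))
  components <- c(intersect(canonical, labs), setdiff(labs, canonical))
  if (length(components) < 2)
    stop("need annotations for at least 2 components", call. = FALSE)
  centroids <- matrix(NA_real_, length(components), 3,
                      dimnames = list(components, c("r", "g", "b")))
  n_points <- setNames(integer(length(components)), components)
  for (comp in components) {
    sel <- annotations$label == comp
    rows <- ys[sel] + 1L; cols <- xs[sel] + 1L
    px <- cbind(image[cbind(rows, cols, 1L)],
                image[cbind(rows, cols, 2L)],
                image[cbind(rows, cols, 3L)])
    centroids[comp, ] <- colMeans(px)
    n_points[comp] <- sum(sel)
  }
  structure(list(components = components, centroids = centroids,
                 n_points = n_points),
            class = "color_reference")
}

#' Sample reference annotations from ground-truth masks
#'
#' Emulates a human annotator on a synthetic image: draws `n_per_label`
#' random pixel coordinates from each component's truth mask. Elastin points
#' are drawn from the union of the lamina and fiber masks.
#'
#' @param truth the `truth` element of a [gen_histology_image()] result.
#' @param n_per_label points per component (30 in the standard protocol).
#' @return data frame with columns `label`, `x`, `y` (0-based).
#' @export
sample_annotations <- function(truth, n_per_label = 30) {
  masks <- truth$masks
  comp_masks <- list(elastin = masks$lamina | masks$fibers,
                     collagen = masks$collagen,
                     smooth_muscle = masks$smooth_muscle,
                     background = masks$background)
  out <- list()
  for (comp in names(comp_masks)) {
    idx <- which(comp_masks[[comp]])
    if (length(idx) == 0) next
    pick <- idx[sample.int(length(idx), min(n_per_label, length(idx)),
                           replace = length(idx) < n_per_label)]
    h <- nrow(comp_masks[[comp]])
    out[[comp]] <- data.frame(label = comp,
                              x = (pick - 1L) %/% h,   # column, 0-based
                              y = (pick - 1L) %% h)    # row, 0-based
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify ROI pixels by nearest RGB centroid
#'
#' Assigns every ROI pixel the component whose reference centroid is nearest
#' in Euclidean RGB distance. Exact ties go to the earlier-listed component
#' of the reference.
#'
#' @param image `h x w x 3` RGB array, 0--255.
#' @param ref a [build_color_reference()] result, or a k x 3 matrix of
#'   centroids with component rownames.
#' @param roi logical media mask of the same height/width; default the whole
#'   frame.
#' @return a `label_map` list with `labels` (integer matrix, `NA` outside
#'   the ROI), `components` and `roi`.
#' @export
classify_pixels <- function(image, ref, roi = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (inherits(ref, "color_reference")) {
    centroids <- ref$centroids; components <- ref$components
  } else {
    centroids <- as.matrix(ref); components <- rownames(centroids)
  }
  if (is.null(components))
    stop("`ref` centroids must carry component names", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  check_mask(roi, "roi")
  check_same_shape(image, roi, "image", "roi")
  idx <- which(roi)
  if (length(idx) == 0)
    stop("`roi` is empty", call. = FALSE)
  px <- cbind(as.vector(image[, , 1])[idx],
              as.vector(image[, , 2])[idx],
              as.vector(image[, , 3])[idx])
  d2 <- matrix(vapply(seq_len(nrow(centroids)), function(k) {
    (px[, 1] - centroids[k, 1])^2 + (px[, 2] - centroids[k, 2])^2 +
      (px[, 3] - centroids[k, 3])^2
  }, numeric(length(idx))), nrow = length(idx))
  assign <- max.col(-d2, ties.method = "first")
  labels <- matrix(NA_integer_, h, w)
  labels[idx] <- assign
  structure(list(labels = labels, components = components, roi = roi),
            class = "label_map")
}

#' Area fractions of a label map
#'
#' Pixel count of each component divided by the total ROI pixel count.
#' Background pixels stay in the denominator, so the fractions form a
#' probability vector over all components including background.
#'
#' @param label_map a [classify_pixels()] result.
#' @return a `composition_result` list with `fractions` (named numeric,
#'   sums to 1) and `roi_area_px`.
#' @export
area_fractions <- function(label_map) {
  stopifnot(inherits(label_map, "label_map"))
  lab <- label_map$labels[label_map$roi]
  n <- length(lab)
  if (n == 0) stop("empty ROI", call. = FALSE)
  counts <- tabulate(lab, nbins = length(label_map$components))
  structure(list(fractions = setNames(counts / n, label_map$components),
                 roi_area_px = n),
            class = "composition_result")
}
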