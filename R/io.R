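#' Read and write peel-trace CSV files
#'
#' Traces are stored as two-column CSV with header `time_s,force_N`.
#'
#' @param record a [peel_record()] (for writing).
#' @param path file path.
#' @return `read_trace_csv()` returns a data frame with columns `time_s`
#'   and `force_N`.
#' @export
write_trace_csv <- function(record, path) {
  stopifnot(inherits(record, "peel_record"))
  write.csv(data.frame(time_s = record$time, force_N = record$force),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(d)))
    stop("trace CSV must have columns `time_s` and `force_N`: ", path,
         call. = FALSE)
  d
}

#' Read and write RGB images and binary masks as PNG
#'
#' Images are 8-bit RGB PNG; masks are single-channel PNG holding 0 or 255.
#'
#' @param image `h x w x 3` array, 0--255.
#' @param mask logical matrix.
#' @param path file path.
#' @return readers return the array (0--255) or logical matrix.
#' @export
write_rgb_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname write_rgb_png
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask, "mask")
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Read and write point annotations
#'
#' Annotations are CSV with columns `label,x,y`; `x` is the 0-based column
#' and `y` the 0-based row of the annotated pixel.
#'
#' @param annotations data frame with columns `label`, `x`, `y`.
#' @param path file path.
#' @return `read_annotations_csv()` returns the data frame.
#' @export
write_annotations_csv <- function(annotations, path) {
  stopifnot(all(c("label", "x", "y") %in% names(annotations)))
  write.csv(annotations[, c("label", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("label", "x", "y") %in% names(d)))
    stop("annotation CSV must have columns label, x, y: ", path,
         call. = FALSE)
  d
}

#' Read a study manifest
#'
#' The manifest links every sample to its files and metadata: columns
#' `sample_id`, `rat_id`, `group`, `direction`, `width_1`..`width_5` (mm),
#' and relative paths `trace_file`, `em_file`, `azan_file`, `roi_file`,
#' `annotations_em`, `annotations_azan` (empty when absent). Sample ids
#' must be unique.
#'
#' @param path manifest CSV path.
#' @return tibble of the manifest.
#' @export
read_manifest <- function(path) {
  d <- read.csv(path)
  need <- c("sample_id", "rat_id", "group", "direction",
            paste0("width_", 1:5))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("manifest sample_ids must be unique", call. = FALSE)
  tibble::as_tibble(d)
}
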