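#' Write a synthetic study to disk
#'
#' Generates the full three-group dataset ([gen_group_dataset()]) and writes
#' it in the on-disk layout consumed by [analyze_study()]: per-sample trace
#' CSVs, EM and Azan images with ROI masks and annotation CSVs, truth JSON
#' sidecars, a manifest linking everything, and a provenance record holding
#' the seed, parameters and package version. Re-running with the same seed
#' reproduces the files byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param spec study design, a named list of [group_spec()]s.
#' @param seed integer seed for the whole study.
#' @return the manifest tibble, invisibly; written as `manifest.csv`.
#' @export
simulate_study <- function(out_dir, spec = default_study_spec(), seed = 1) {
  dataset <- gen_group_dataset(spec, seed, materialize = TRUE)
  for (sub in c("traces", "images", "masks", "annotations", "truth"))
    dir.create(file.path(out_dir, sub), recursive = TRUE,
               showWarnings = FALSE)
  samples <- dataset$samples
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    id <- s$sample_id
    rec <- dataset$traces[[id]]
    trace_file <- file.path("traces", paste0(id, ".csv"))
    write_trace_csv(rec, file.path(out_dir, trace_file))
    em_file <- azan_file <- roi_file <- ann_em <- ann_azan <- ""
    truth <- list(S_d_true = s$S_d_true, a_true = s$a_true,
                  b_true = s$b_true, c_true = s$c_true,
                  fail_time = s$fail_time)
    if (isTRUE(s$has_histo)) {
      em <- dataset$em[[id]]; az <- dataset$azan[[id]]
      em_file <- file.path("images", paste0(id, "_EM.png"))
      azan_file <- file.path("images", paste0(id, "_Azan.png"))
      roi_file <- file.path("masks", paste0(id, "_roi.png"))
      ann_em <- file.path("annotations", paste0(id, "_EM.csv"))
      ann_azan <- file.path("annotations", paste0(id, "_Azan.csv"))
      write_rgb_png(em$image, file.path(out_dir, em_file))
      write_rgb_png(az$image, file.path(out_dir, azan_file))
      write_mask_png(em$roi, file.path(out_dir, roi_file))
      # annotation points emulate a human marking clear example pixels
      set.seed(s$em_seed)
      write_annotations_csv(sample_annotations(em$truth),
                            file.path(out_dir, ann_em))
      set.seed(s$azan_seed)
      write_annotations_csv(sample_annotations(az$truth),
                            file.path(out_dir, ann_azan))
      truth$lambda_fibers <- em$truth$lambda_fibers
      truth$fractions_em <- as.list(em$truth$fractions)
      truth$fractions_azan <- as.list(az$truth$fractions)
      truth$px_size <- em$px_size
    }
    jsonlite::write_json(truth,
                         file.path(out_dir, "truth", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- tibble::tibble(
      sample_id = id, rat_id = s$rat_id, group = s$group,
      direction = s$direction,
      width_1 = mean(rec$widths) * 1e3, width_2 = mean(rec$widths) * 1e3,
      width_3 = mean(rec$widths) * 1e3, width_4 = mean(rec$widths) * 1e3,
      width_5 = mean(rec$widths) * 1e3,
      trace_file = trace_file, em_file = em_file, azan_file = azan_file,
      roi_file = roi_file, annotations_em = ann_em,
      annotations_azan = ann_azan)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  prov <- list(seed = seed,
               package = "delamina",
               version = as.character(utils::packageVersion("delamina")),
               generated = "synthetic study",
               groups = lapply(spec, function(g)
                 g[setdiff(names(g), c("trace", "histo"))]))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

analyze_one_sample <- function(s, dir, px_size, drop_fraction, threshold,
                               min_area, circularity_range, iterations) {
  out <- tibble::tibble(
    sample_id = s$sample_id, rat_id = s$rat_id, group = s$group,
    direction = s$direction, S_d = NA_real_, b = NA_real_, c = NA_real_,
    rss = NA_real_, converged = NA, lambda_ela = NA_real_,
    lambda_col = NA_real_, lambda_fibers = NA_real_, status = "ok")
  widths_m <- as.numeric(unlist(s[paste0("width_", 1:5)])) * 1e-3
  has <- function(col) col %in% names(s) && !is.na(s[[col]]) &&
    nzchar(s[[col]])
  if (has("trace_file")) {
    tr <- read_trace_csv(file.path(dir, s$trace_file))
    rec <- peel_record(tr$time_s, tr$force_N, widths_m, group = s$group,
                       direction = s$direction, rat_id = s$rat_id,
                       sample_id = s$sample_id)
    fit <- delamination_strength(rec, drop_fraction)
    out$S_d <- fit$S_d; out$b <- fit$b; out$c <- fit$c
    out$rss <- fit$rss; out$converged <- fit$converged
  }
  if (has("em_file")) {
    img <- read_rgb_png(file.path(dir, s$em_file))
    roi <- if (has("roi_file")) read_mask_png(file.path(dir, s$roi_file))
           else NULL
    ann <- read_annotations_csv(file.path(dir, s$annotations_em))
    ref <- build_color_reference(img, ann)
    comp <- area_fractions(classify_pixels(img, ref, roi))
    out$lambda_ela <- comp$fractions[["elastin"]]
    ext <- extract_interlaminar(img, roi, px_size, threshold, min_area,
                                circularity_range, iterations)
    out$lambda_fibers <- ext$lambda_fibers
  }
  if (has("azan_file")) {
    img <- read_rgb_png(file.path(dir, s$azan_file))
    roi <- if (has("roi_file")) read_mask_png(file.path(dir, s$roi_file))
           else NULL
    ann <- read_annotations_csv(file.path(dir, s$annotations_azan))
    ref <- build_color_reference(img, ann)
    comp <- area_fractions(classify_pixels(img, ref, roi))
    out$lambda_col <- comp$fractions[["collagen"]]
  }
  out
}

#' Analyze every sample of a study directory
#'
#' Reads the manifest and, per sample, fits the delamination strength from
#' its trace (when present), the elastin and collagen area fractions from
#' its EM / Azan images, and the interlaminar-fiber fraction from the EM
#' image. A failure in one sample is caught, recorded in that sample's
#' `status` column, and does not stop the remaining samples.
#'
#' @param dir study directory written by [simulate_study()] (or laid out the
#'   same way for real data).
#' @param px_size micrometers per pixel of the images.
#' @param drop_fraction failure-truncation threshold, see
#'   [truncate_at_failure()].
#' @param threshold fixed green threshold or `NULL` for automatic.
#' @param min_area,circularity_range,iterations particle-filter settings,
#'   see [el_mask()].
#' @param write write `results.csv` into `dir`.
#' @return tibble with one row per manifest sample: fitted `S_d`, `b`, `c`,
#'   `rss`, `converged`, `lambda_ela`, `lambda_col`, `lambda_fibers`,
#'   `status`.
#' @export
analyze_study <- function(dir, px_size = 0.25, drop_fraction = 0.5,
                          threshold = NULL, min_area = 0.1,
                          circularity_range = c(0, 0.3), iterations = 5,
                          write = FALSE) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- manifest[i, ]
    tryCatch(
      analyze_one_sample(s, dir, px_size, drop_fraction, threshold,
                         min_area, circularity_range, iterations),
      error = function(e) tibble::tibble(
        sample_id = s$sample_id, rat_id = s$rat_id, group = s$group,
        direction = s$direction, S_d = NA_real_, b = NA_real_,
        c = NA_real_, rss = NA_real_, converged = NA,
        lambda_ela = NA_real_, lambda_col = NA_real_,
        lambda_fibers = NA_real_,
        status = paste("error:", conditionMessage(e))))
  })
  res <- do.call(rbind, rows)
  if (write) write.csv(res, file.path(dir, "results.csv"),
                       row.names = FALSE)
  res
}

#' Group statistics report for a results table
#'
#' Produces the study-level statistics: mean +/- SD summaries per cell,
#' two-way (group x direction) ANOVA of the delamination strength,
#' Tukey--Kramer all-pairs comparisons per measure, and the Pearson
#' correlation between delamination strength and interlaminar-fiber
#' fraction within each test direction (using only samples carrying both
#' measurements).
#'
#' @param results tibble from [analyze_study()].
#' @param alpha significance level.
#' @param aggregate_rats see [two_way_anova()].
#' @return list with `summaries` (named list of tibbles), `anova`,
#'   `tukey` (named list of tibbles) and `correlations` (tibble with one
#'   row per direction).
#' @export
report_study <- function(results, alpha = 0.05, aggregate_rats = FALSE) {
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  measures <- c(S_d = "S_d", lambda_ela = "lambda_ela",
                lambda_col = "lambda_col", lambda_fibers = "lambda_fibers")
  present <- measures[vapply(measures, function(m)
    any(is.finite(results[[m]])), logical(1))]
  if (length(present) == 0) stop("no measured columns present",
                                 call. = FALSE)
  summaries <- lapply(present, function(m)
    summarize_cells(results, m,
                    by = if (m == "S_d") c("group", "direction") else
                      "group"))
  anova <- if ("S_d" %in% present &&
               length(unique(results$group[is.finite(results$S_d)])) >= 2)
    two_way_anova(results, "S_d", aggregate_rats, alpha) else NULL
  tukey <- lapply(present, function(m) {
    d <- results[is.finite(results[[m]]), ]
    tukey_kramer(split(d[[m]], d$group), alpha = alpha)
  })
  both <- results[is.finite(results$S_d) &
                    is.finite(results$lambda_fibers), ]
  correlations <- do.call(rbind, lapply(c("theta", "z"), function(dir) {
    d <- both[both$direction == dir, ]
    if (nrow(d) < 3)
      return(tibble::tibble(direction = dir, n = nrow(d), R = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            significant = NA))
    ct <- pearson_r_test(d$S_d, d$lambda_fibers, alpha)
    tibble::tibble(direction = dir, n = ct$n, R = ct$R,
                   statistic = ct$statistic, p_value = ct$p_value,
                   significant = ct$significant)
  }))
  list(summaries = summaries, anova = anova, tukey = tukey,
       correlations = correlations)
}

#' Replicate the whole study and count significant comparisons
#'
#' Repeats the synthetic study end to end `n_reps` times: per replicate it
#' draws fresh ground truth, fits every peel trace through the full
#' tension/truncation/sigmoid chain, runs the interlaminar extraction on
#' every generated EM image, and applies the Tukey--Kramer comparison to
#' both measures. Traces and images are streamed one at a time, so memory
#' stays flat.
#'
#' @param spec study design.
#' @param n_reps number of replicate studies.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param alpha significance level.
#' @return list with `pairwise`, a tibble of per-comparison significance
#'   fractions over replicates (`measure`, `comparison`, `frac_significant`),
#'   and `frac_all_significant`, the fraction of replicates in which every
#'   pairwise comparison of both measures was significant.
#' @export
replicate_power <- function(spec = default_study_spec(), n_reps = 50,
                            seed = 1, alpha = 0.05) {
  spec_by_name <- setNames(spec, vapply(spec, `[[`, "", "name"))
  tally <- NULL; all_sig <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    samples <- draw_study_params(spec, seed + r)
    sd_vals <- numeric(nrow(samples)); lf_vals <- rep(NA_real_,
                                                      nrow(samples))
    for (i in seq_len(nrow(samples))) {
      row <- samples[i, ]
      g <- spec_by_name[[row$group]]
      targs <- c(list(S_d_true = row$S_d_true, a_true = row$a_true,
                      b_true = row$b_true, c_true = row$c_true,
                      fail_time = row$fail_time, seed = row$trace_seed),
                 g$trace)
      rec <- gen_peel_trace(do.call(peel_trace_params, targs))$record
      fit <- delamination_strength(rec)
      sd_vals[i] <- fit$S_d
      if (isTRUE(row$has_histo)) {
        em <- gen_histology_image(histo_params_for_row(row, g, "EM"))
        lf_vals[i] <- extract_interlaminar(em$image, em$roi,
                                           em$px_size)$lambda_fibers
      }
    }
    res <- list(
      S_d = tukey_kramer(split(sd_vals, samples$group), alpha = alpha),
      lambda_fibers = tukey_kramer(
        split(lf_vals[!is.na(lf_vals)],
              samples$group[!is.na(lf_vals)]), alpha = alpha))
    rep_tab <- do.call(rbind, lapply(names(res), function(m)
      tibble::tibble(measure = m, comparison = res[[m]]$comparison,
                     significant = res[[m]]$significant)))
    all_sig[r] <- all(rep_tab$significant)
    tally <- if (is.null(tally)) rep_tab else {
      stopifnot(identical(tally$comparison, rep_tab$comparison))
      tally$significant <- tally$significant + rep_tab$significant
      tally
    }
    if (r == 1) tally$significant <- as.integer(tally$significant)
  }
  tally$frac_significant <- tally$significant / n_reps
  list(pairwise = tibble::tibble(measure = tally$measure,
                                 comparison = tally$comparison,
                                 frac_significant = tally$frac_significant),
       frac_all_significant = mean(all_sig))
}
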