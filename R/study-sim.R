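#' Specification of one synthetic study group
#'
#' Describes how per-sample ground truth is drawn for one treatment group:
#' delamination strength varies between rats (SD `sd_rat`) and between
#' samples within a rat (SD `sd_sample`); histology targets vary between
#' images. Defaults for the three-group study live in
#' [default_study_spec()].
#'
#' @param name group label.
#' @param n_rats number of animals.
#' @param samples_per_rat peel samples per rat *per direction* (both the
#'   circumferential `theta` and longitudinal `z` directions are tested).
#' @param sd_mean group mean delamination strength, N/m.
#' @param sd_rat,sd_sample between-rat and within-rat SD of the true
#'   delamination strength, N/m.
#' @param n_histo number of histology images for the group (attached to the
#'   first `n_histo` peel samples, so those carry both measurements).
#' @param lambda_fibers_mean,lambda_fibers_sd mean and between-image SD of
#'   the true interlaminar-fiber area fraction.
#' @param lambda_ela_mean,lambda_ela_sd mean and between-image SD of the
#'   true elastin area fraction (laminas + fibers).
#' @param lambda_col_mean,lambda_col_sd mean and between-image SD of the
#'   true collagen area fraction.
#' @param trace named list of [peel_trace_params()] overrides shared by the
#'   group (e.g. `noise_sd`).
#' @param histo named list of [histo_image_params()] overrides shared by the
#'   group (e.g. `color_noise_sd`, image size).
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n_rats, samples_per_rat = 2, sd_mean = 20,
                       sd_rat = 3, sd_sample = 4, n_histo = 9,
                       lambda_fibers_mean = 0.104, lambda_fibers_sd = 0.016,
                       lambda_ela_mean = 0.569, lambda_ela_sd = 0.02,
                       lambda_col_mean = 0.125, lambda_col_sd = 0.06,
                       trace = list(), histo = list()) {
  stopifnot(is.character(name), length(name) == 1)
  check_number(n_rats, "n_rats", min = 0)
  check_number(samples_per_rat, "samples_per_rat", min = 0)
  check_number(sd_mean, "sd_mean", positive = TRUE)
  structure(list(name = name, n_rats = as.integer(n_rats),
                 samples_per_rat = as.integer(samples_per_rat),
                 sd_mean = sd_mean, sd_rat = sd_rat, sd_sample = sd_sample,
                 n_histo = as.integer(n_histo),
                 lambda_fibers_mean = lambda_fibers_mean,
                 lambda_fibers_sd = lambda_fibers_sd,
                 lambda_ela_mean = lambda_ela_mean,
                 lambda_ela_sd = lambda_ela_sd,
                 lambda_col_mean = lambda_col_mean,
                 lambda_col_sd = lambda_col_sd,
                 trace = trace, histo = histo),
            class = "group_spec")
}

#' Default three-group study design
#'
#' Mirrors the reported study conditions of the rat aortic-dissection model:
#' group mean delamination strengths 20 / 16 / 11 N/m with within-group SDs
#' of roughly 5 / 2.3 / 2.9 N/m and per-direction sample counts 20 / 10 / 14;
#' interlaminar-fiber fractions 10.4 / 8.6 / 5.2 % with SDs 1.6 / 1.6 /
#' 1.2 %; elastin fractions 56.9 / 57.1 / 47.2 %; collagen fractions 12.5 /
#' 23.3 / 25.5 % with SDs about 6 %; nine histology images per group.
#'
#' @param noise_sd force-noise SD (N) shared by all traces (default 5% of
#'   the Control plateau force).
#' @param color_noise_sd per-channel color-noise SD shared by all images.
#' @return named list of three [group_spec()] objects.
#' @export
default_study_spec <- function(noise_sd = 0.003, color_noise_sd = 8) {
  tr <- list(noise_sd = noise_sd)
  hi <- list(color_noise_sd = color_noise_sd)
  list(
    Control = group_spec("Control", n_rats = 10, samples_per_rat = 2,
                         sd_mean = 20, sd_rat = 3, sd_sample = 4,
                         n_histo = 9,
                         lambda_fibers_mean = 0.104, lambda_fibers_sd = 0.016,
                         lambda_ela_mean = 0.569, lambda_col_mean = 0.125,
                         lambda_col_sd = 0.06, trace = tr, histo = hi),
    `Pre-dissection` = group_spec("Pre-dissection", n_rats = 5,
                                  samples_per_rat = 2, sd_mean = 16,
                                  sd_rat = 1.2, sd_sample = 2, n_histo = 9,
                                  lambda_fibers_mean = 0.086,
                                  lambda_fibers_sd = 0.016,
                                  lambda_ela_mean = 0.571,
                                  lambda_col_mean = 0.233,
                                  lambda_col_sd = 0.06,
                                  trace = tr, histo = hi),
    Dissection = group_spec("Dissection", n_rats = 7, samples_per_rat = 2,
                            sd_mean = 11, sd_rat = 1.5, sd_sample = 2.5,
                            n_histo = 9,
                            lambda_fibers_mean = 0.052,
                            lambda_fibers_sd = 0.012,
                            lambda_ela_mean = 0.472,
                            lambda_col_mean = 0.255, lambda_col_sd = 0.056,
                            trace = tr, histo = hi)
  )
}

# draw the per-sample ground-truth table for a study (no images or traces
# materialized yet); reproducible for a fixed seed
draw_study_params <- function(spec = default_study_spec(), seed = 1) {
  if (length(spec) < 1) stop("need at least one group", call. = FALSE)
  if (inherits(spec, "group_spec")) spec <- list(spec)
  set.seed(seed)
  rows <- list()
  for (g in spec) {
    stopifnot(inherits(g, "group_spec"))
    gslug <- gsub("[^A-Za-z0-9]+", "", g$name)
    samp <- list()
    if (g$n_rats > 0 && g$samples_per_rat > 0) {
      for (r in seq_len(g$n_rats)) {
        rat_id <- sprintf("%s_r%02d", gslug, r)
        rat_eff <- rnorm(1, 0, g$sd_rat)
        for (dir in c("theta", "z")) {
          for (s in seq_len(g$samples_per_rat)) {
            sd_true <- max(1, g$sd_mean + rat_eff + rnorm(1, 0, g$sd_sample))
            samp[[length(samp) + 1]] <- tibble::tibble(
              group = g$name, rat_id = rat_id, direction = dir,
              sample_id = sprintf("%s_%s_s%02d", rat_id, dir, s),
              S_d_true = sd_true,
              a_true = exp(rnorm(1, log(50), 0.3)),
              b_true = exp(rnorm(1, log(0.5), 0.2)),
              c_true = rnorm(1, 10, 2),
              fail_time = runif(1, 50, 75),
              trace_seed = sample.int(.Machine$integer.max, 1))
          }
        }
      }
    }
    tab <- if (length(samp)) do.call(rbind, samp) else tibble::tibble(
      group = character(), rat_id = character(), direction = character(),
      sample_id = character(), S_d_true = numeric(), a_true = numeric(),
      b_true = numeric(), c_true = numeric(), fail_time = numeric(),
      trace_seed = integer())
    n <- nrow(tab)
    has_histo <- rep(FALSE, n)
    if (n > 0) has_histo[seq_len(min(g$n_histo, n))] <- TRUE
    tab$has_histo <- has_histo
    tab$lambda_fibers_target <- ifelse(
      has_histo, pmax(0.01, rnorm(n, g$lambda_fibers_mean,
                                  g$lambda_fibers_sd)), NA_real_)
    tab$lambda_ela_target <- ifelse(
      has_histo, pmax(0.35, rnorm(n, g$lambda_ela_mean, g$lambda_ela_sd)),
      NA_real_)
    # collagen must fit in the non-elastin remainder next to the fixed 5%
    # background allocation (with margin for the lamina-thickness floor)
    tab$lambda_col_target <- ifelse(
      has_histo,
      pmin(0.9 * (1 - tab$lambda_ela_target) - 0.05,
           pmax(0.03, rnorm(n, g$lambda_col_mean, g$lambda_col_sd))),
      NA_real_)
    tab$em_seed <- ifelse(has_histo, sample.int(.Machine$integer.max, n),
                          NA_integer_)
    tab$azan_seed <- ifelse(has_histo, sample.int(.Machine$integer.max, n),
                            NA_integer_)
    if (n == 0) {
      tab$has_histo <- logical(); tab$lambda_fibers_target <- numeric()
      tab$lambda_ela_target <- numeric(); tab$lambda_col_target <- numeric()
      tab$em_seed <- integer(); tab$azan_seed <- integer()
    }
    rows[[length(rows) + 1]] <- tab
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  out
}

# materialize the histology parameter sets for one sample row; the lamina
# thickness is solved from the drawn elastin and fiber targets so that the
# realized elastin fraction tracks the target
histo_params_for_row <- function(row, g, stain = c("EM", "Azan")) {
  stain <- match.arg(stain)
  defaults <- histo_image_params()
  over <- g$histo
  geom <- function(nm) if (!is.null(over[[nm]])) over[[nm]] else defaults[[nm]]
  height <- geom("height"); px <- geom("px_size"); nl <- geom("n_laminas")
  # laminas must stay thicker than the 11 px kill width of the 5-iteration
  # opening, with margin for the waviness tilt
  lam_frac <- row$lambda_ela_target - row$lambda_fibers_target
  t_um <- max(13.5 * px, lam_frac * height * px / nl)
  args <- list(height = height, width = geom("width"), px_size = px,
               n_laminas = nl, lamina_thickness = t_um,
               fiber_fraction = row$lambda_fibers_target,
               target_fractions = c(collagen = row$lambda_col_target,
                                    background = 0.05),
               palette = if (stain == "EM") em_palette() else azan_palette(),
               seed = if (stain == "EM") row$em_seed else row$azan_seed)
  keep <- setdiff(names(over), names(args))
  do.call(histo_image_params, c(args, over[keep]))
}

#' Generate a full synthetic study dataset in memory
#'
#' Draws per-sample ground truth for every group (reproducibly for a fixed
#' seed), then materializes a peel trace for every sample and an
#' Elastica--Masson plus an Azan image for the samples flagged for
#' histology.
#'
#' @param spec named list of [group_spec()] objects (default
#'   [default_study_spec()]).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param materialize if `FALSE`, return only the ground-truth sample table
#'   (fast; used by power replications that stream samples one at a time).
#' @return a list with `samples` (tibble of per-sample ground truth),
#'   `traces` (named list of [peel_record()]s) and, for histology samples,
#'   `em` / `azan` (named lists of [gen_histology_image()] outputs).
#' @export
gen_group_dataset <- function(spec = default_study_spec(), seed = 1,
                              materialize = TRUE) {
  samples <- draw_study_params(spec, seed)
  if (!materialize) return(list(samples = samples))
  spec_by_name <- setNames(attr(samples, "spec"),
                           vapply(attr(samples, "spec"), `[[`, "", "name"))
  traces <- list(); em <- list(); azan <- list()
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    g <- spec_by_name[[row$group]]
    targs <- c(list(S_d_true = row$S_d_true, a_true = row$a_true,
                    b_true = row$b_true, c_true = row$c_true,
                    fail_time = row$fail_time, seed = row$trace_seed),
               g$trace)
    tr <- gen_peel_trace(do.call(peel_trace_params, targs),
                         group = row$group, direction = row$direction,
                         rat_id = row$rat_id, sample_id = row$sample_id)
    traces[[row$sample_id]] <- tr$record
    if (isTRUE(row$has_histo)) {
      em[[row$sample_id]] <-
        gen_histology_image(histo_params_for_row(row, g, "EM"))
      azan[[row$sample_id]] <-
        gen_histology_image(histo_params_for_row(row, g, "Azan"))
    }
  }
  list(samples = samples, traces = traces, em = em, azan = azan)
}
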