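#' Two-way fixed-effects ANOVA
#'
#' Group x direction analysis of variance of one response, reported as a
#' tidy sums-of-squares decomposition. The study design has several samples
#' per animal; because the exact repeated-measures error strata are a
#' modelling choice, the default analyses per-sample values with fixed
#' effects, and `aggregate_rats = TRUE` first averages samples to one value
#' per rat x direction cell (a conservative subject-level analysis).
#'
#' When the response is perfectly constant the F statistics are reported as
#' 0 with p = 1 (no evidence of any effect) rather than the indeterminate
#' 0/0.
#'
#' @param data data frame with columns `group`, `direction`, optionally
#'   `rat_id`, and the response.
#' @param response name of the response column.
#' @param aggregate_rats average to rat x direction means before testing.
#' @param alpha significance level for the `significant` flag.
#' @return tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value`, `significant`.
#' @export
two_way_anova <- function(data, response, aggregate_rats = FALSE,
                          alpha = 0.05) {
  stopifnot(all(c("group", "direction", response) %in% names(data)))
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  if (length(unique(d$group)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (length(unique(d$direction)) < 2)
    stop("both directions must be present", call. = FALSE)
  if (aggregate_rats) {
    stopifnot("rat_id" %in% names(d))
    d <- aggregate(d[[response]],
                   by = list(group = d$group, direction = d$direction,
                             rat_id = d$rat_id),
                   FUN = mean)
    names(d)[4] <- response
  }
  cells <- table(d$group, d$direction)
  if (any(cells < 2))
    stop("every group x direction cell needs at least 2 observations",
         call. = FALSE)
  d$group <- factor(d$group); d$direction <- factor(d$direction)
  fml <- stats::as.formula(paste0("`", response, "` ~ group * direction"))
  fit <- aov(fml, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  tot_ss <- sum(tab[["Sum Sq"]])
  res <- tibble::tibble(term = terms, df = tab[["Df"]],
                        sumsq = tab[["Sum Sq"]], meansq = tab[["Mean Sq"]],
                        statistic = tab[["F value"]],
                        p_value = tab[["Pr(>F)"]])
  if (tot_ss <= .Machine$double.eps * nrow(d)) { # constant response
    eff <- res$term != "Residuals"
    res$statistic[eff] <- 0
    res$p_value[eff] <- 1
  }
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}

#' Tukey--Kramer all-pairs comparison
#'
#' Pairwise comparison of k group means using the studentized-range
#' distribution with the Kramer unequal-sample-size standard error:
#' \eqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{MSE/2 (1/n_i + 1/n_j)}}
#' with the mean-square error pooled over all groups (df = N - k), and
#' p-values from `ptukey(q, k, N - k)`.
#'
#' @param values either a named list of numeric vectors (one per group), or
#'   a numeric vector paired with `groups`.
#' @param groups group labels when `values` is a vector.
#' @param alpha significance level.
#' @return tibble with one row per pair: `comparison`, `group1`, `group2`,
#'   `estimate` (mean difference, group1 - group2), `q`, `df`, `p_value`,
#'   `significant`.
#' @examples
#' set.seed(1)
#' tukey_kramer(list(a = rnorm(9, 10), b = rnorm(9, 12), c = rnorm(9, 15)))
#' @export
tukey_kramer <- function(values, groups = NULL, alpha = 0.05) {
  if (!is.list(values)) {
    stopifnot(!is.null(groups), length(groups) == length(values))
    values <- split(as.numeric(values), as.character(groups))
  }
  k <- length(values)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(values, length, integer(1))
  bad <- names(values)[ns < 2]
  if (length(bad))
    stop(sprintf("group `%s` has fewer than 2 values", bad[1]),
         call. = FALSE)
  means <- vapply(values, mean, numeric(1))
  df <- sum(ns) - k
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2),
                    numeric(1))) / df
  nm <- names(values)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    diff <- means[i] - means[j]
    q <- if (se > 0) abs(diff) / se else if (abs(diff) > 0) Inf else 0
    p <- 1 - ptukey(q, nmeans = k, df = df)
    out[[length(out) + 1]] <- tibble::tibble(
      comparison = paste(nm[i], "-", nm[j]), group1 = nm[i], group2 = nm[j],
      estimate = unname(diff), q = unname(q), df = df, p_value = unname(p),
      significant = p < alpha)
  }
  do.call(rbind, out)
}

#' Pearson correlation with Student's t-test
#'
#' Pearson's R with the two-sided p-value from
#' \eqn{t = R \sqrt{(n-2)/(1-R^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @param alpha significance level.
#' @return list with `R`, `statistic`, `df`, `p_value`, `n`, `significant`.
#' @export
pearson_r_test <- function(x, y, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t), df)
  }
  list(R = r, statistic = t, df = df, p_value = p, n = n,
       significant = p < alpha)
}

#' Mean and SD summaries per cell
#'
#' Sample mean and (n-1)-denominator SD of a response within each cell of
#' the grouping columns, with the sample count `n` and, when `rat_id` is
#' present, the animal count `N`. A single-value cell reports SD 0 with
#' `n = 1`.
#'
#' @param data data frame.
#' @param response response column name.
#' @param by character vector of grouping column names.
#' @return tibble with the grouping columns plus `n`, `N` (if available),
#'   `mean`, `sd`.
#' @export
summarize_cells <- function(data, response, by = "group") {
  stopifnot(all(c(by, response) %in% names(data)))
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  if (nrow(d) == 0) stop("no finite values to summarize", call. = FALSE)
  key <- interaction(d[by], drop = TRUE, lex.order = TRUE)
  parts <- split(d, key)
  out <- lapply(parts, function(p) {
    row <- p[1, by, drop = FALSE]
    row$n <- nrow(p)
    if ("rat_id" %in% names(p)) row$N <- length(unique(p$rat_id))
    row$mean <- mean(p[[response]])
    row$sd <- if (nrow(p) > 1) sd(p[[response]]) else 0
    row
  })
  tibble::as_tibble(do.call(rbind, out))
}
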