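#' Per-sample normalization factors for the Express test
#'
#' Factors equalize the basis-region count totals across samples: the
#' factor of sample `s` is the mean over all samples of the basis totals
#' divided by the basis total of `s`; normalized counts are raw counts
#' times the factor, so after normalization every sample has the same
#' basis total. The basis is either every region or a user list (e.g.
#' housekeeping genes).
#'
#' @param counts tibble with a `region` column and one numeric column per
#'   sample.
#' @param samples sample column names to normalize (default: all).
#' @param region_list optional character vector of basis regions; `NULL`
#'   uses all regions.
#' @return tibble with `sample`, `basis_total`, `factor`.
#' @export
compute_normalization <- function(counts, samples = NULL,
                                  region_list = NULL) {
  if (is.null(samples)) samples <- setdiff(names(counts), "region")
  basis <- counts
  if (!is.null(region_list)) {
    missing <- setdiff(region_list, counts$region)
    if (length(missing) > 0) {
      stop("region_list entries absent from counts: ",
           paste(missing, collapse = ", "))
    }
    basis <- counts[counts$region %in% region_list, , drop = FALSE]
  }
  totals <- vapply(samples, function(s) sum(basis[[s]]), double(1))
  if (any(totals == 0)) {
    stop("basis-region total is zero in sample(s): ",
         paste(samples[totals == 0], collapse = ", "))
  }
  tibble(sample = samples, basis_total = unname(totals),
         factor = mean(totals) / unname(totals))
}

#' The Express test: fast two-condition expression screening
#'
#' Computes, per genomic region, the mean and sample variance (divisor
#' `w - 1`) of the read counts in each condition, the two expression ratios
#' `mean_A/mean_B` and `mean_B/mean_A` (a zero denominator is replaced by
#' one), and a confidence value
#' `C = -log10(0.5 * (var_A/mean_A + var_B/mean_B))` when both means are
#' positive. `C` is set to `-1` whenever a condition mean is zero; when
#' both variance-to-mean ratios are zero at positive means, `C` is
#' `Inf`, the maximal-confidence sentinel (serialized as "inf"). High
#' ratios together with a high confidence value flag candidate
#' differentially expressed regions; no statistical test is performed.
#'
#' Single-replicate conditions are allowed: their variance is reported as 0
#' and every result row is flagged `single_replicate`.
#'
#' @param counts tibble with a `region` column and one numeric count column
#'   per sample.
#' @param condition_a,condition_b column names of the samples of conditions
#'   A and B.
#' @param normalization `"none"`, `"all-regions"` or `"region-list"`;
#'   counts are rescaled by [compute_normalization()] factors before any
#'   statistic is computed.
#' @param region_list basis regions for `normalization = "region-list"`.
#' @return object of class `express_test`; see [tidy.express_test()] for
#'   the per-region result table.
#' @export
express_test <- function(counts, condition_a, condition_b,
                         normalization = c("none", "all-regions",
                                           "region-list"),
                         region_list = NULL) {
  normalization <- match.arg(normalization)
  counts <- as_tibble(counts)
  stopifnot("region" %in% names(counts),
            all(c(condition_a, condition_b) %in% names(counts)),
            length(condition_a) >= 1, length(condition_b) >= 1,
            nrow(counts) >= 1)
  samples <- c(condition_a, condition_b)
  if (any(vapply(counts[samples], function(x) any(x < 0), logical(1)))) {
    stop("negative counts")
  }
  factors <- tibble(sample = samples, basis_total = NA_real_, factor = 1)
  if (normalization != "none") {
    factors <- compute_normalization(
      counts, samples,
      region_list = if (normalization == "region-list") region_list)
    for (k in seq_along(samples)) {
      counts[[samples[k]]] <- counts[[samples[k]]] * factors$factor[k]
    }
  }
  a <- as.matrix(counts[condition_a])
  b <- as.matrix(counts[condition_b])
  row_var <- function(x) {
    if (ncol(x) < 2) return(rep(0, nrow(x)))
    apply(x, 1, stats::var)
  }
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  var_a <- row_var(a); var_b <- row_var(b)
  ratio_ab <- mean_a / ifelse(mean_b == 0, 1, mean_b)
  ratio_ba <- mean_b / ifelse(mean_a == 0, 1, mean_a)
  vmr <- 0.5 * (var_a / mean_a + var_b / mean_b)
  confidence <- ifelse(mean_a == 0 | mean_b == 0, -1, -log10(vmr))
  results <- tibble(
    region = counts$region,
    mean_a = mean_a, mean_b = mean_b, var_a = var_a, var_b = var_b,
    ratio_ab = ratio_ab, ratio_ba = ratio_ba, confidence = confidence,
    normalized = normalization != "none",
    single_replicate = length(condition_a) < 2 | length(condition_b) < 2)
  if (any(results$single_replicate)) {
    warning("a condition has a single replicate; variances reported as 0")
  }
  structure(list(results = results, factors = factors,
                 condition_a = condition_a, condition_b = condition_b,
                 normalization = normalization),
            class = "express_test")
}

#' @export
print.express_test <- function(x, ...) {
  cat("<express_test> ", nrow(x$results), " region(s); A: ",
      length(x$condition_a), " sample(s), B: ", length(x$condition_b),
      " sample(s); normalization: ", x$normalization, "\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Tidy the per-region Express-test results
#'
#' @param x an [express_test()] object.
#' @param ... unused.
#' @return tibble with one row per region: means, variances, both ratios,
#'   the confidence value, and flags.
#' @export
tidy.express_test <- function(x, ...) x$results

#' One-row summary of an Express-test run
#'
#' @param x an [express_test()] object.
#' @param ... unused.
#' @return one-row tibble: region count, replicate numbers, normalization
#'   mode, number of zero-mean regions (confidence -1) and the median
#'   finite confidence.
#' @export
glance.express_test <- function(x, ...) {
  r <- x$results
  fin <- r$confidence[is.finite(r$confidence) & r$confidence != -1]
  tibble(n_regions = nrow(r), n_a = length(x$condition_a),
         n_b = length(x$condition_b), normalization = x$normalization,
         n_zero_mean = sum(r$confidence == -1),
         median_confidence = if (length(fin)) median(fin) else NA_real_)
}

#' MA values of Express-test results
#'
#' `M = log2(mean_B / mean_A)` with a zero denominator replaced by one;
#' `A = 0.5 * log2(mean_A * mean_B)` with zero means replaced by one.
#'
#' @param x an [express_test()] object (or its [tidy()] tibble).
#' @return tibble with `region`, `M`, `A`.
#' @export
ma_table <- function(x) {
  r <- if (inherits(x, "express_test")) x$results else as_tibble(x)
  tibble(region = r$region,
         M = log2(r$mean_b / ifelse(r$mean_a == 0, 1, r$mean_a)),
         A = 0.5 * log2(ifelse(r$mean_a == 0, 1, r$mean_a) *
                          ifelse(r$mean_b == 0, 1, r$mean_b)))
}

#' MA plot of an Express-test result
#'
#' @param object an [express_test()] object.
#' @param ... unused.
#' @return a ggplot: per-region log2 fold change (M) against normalized
#'   mean expression (A), coloured by confidence value.
#' @export
autoplot.express_test <- function(object, ...) {
  ma <- ma_table(object)
  ma$confidence <- object$results$confidence
  ma <- ma[is.finite(ma$M), , drop = FALSE]
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$A, y = .data$M,
                                   colour = .data$confidence)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "A (mean expression, log2)",
                  y = "M (log2 fold change B vs A)",
                  colour = "confidence") +
    ggplot2::theme_minimal()
}
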