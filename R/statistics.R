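# Group comparisons and model-validation statistics for the bench study.

#' Compare two groups of measurements
#'
#' Paired-samples t-test when `paired = TRUE`, Welch's t-test otherwise.
#' Significance threshold 0.05. Use [comparison_report()] to apply the
#' Holm-Bonferroni correction across a family of such comparisons.
#'
#' @param a,b numeric vectors (equal length when paired), `n >= 3` each.
#' @param paired logical.
#' @param label comparison label.
#' @return list of class `group_comparison` with means, SDs, `t`, `df`,
#'   `p_value` and the test used.
#' @export
compare_groups <- function(a, b, paired = FALSE, label = "A vs B") {
  if (length(a) < 3L || length(b) < 3L) stop("need n >= 3 per group")
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal lengths")
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate test: zero variance in both groups")
  tt <- t.test(a, b, paired = paired, var.equal = FALSE)
  structure(list(label = label,
                 mean_a = mean(a), sd_a = sd(a),
                 mean_b = mean(b), sd_b = sd(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 test = if (paired) "paired t-test" else "Welch t-test",
                 significant = tt$p.value < 0.05),
            class = "group_comparison")
}

#' Holm-Bonferroni correction across a family of comparisons
#'
#' @param comparisons list of [compare_groups()] results, or a numeric
#'   vector of raw p-values.
#' @param alpha familywise significance level (default 0.05).
#' @return data frame of class `comparison_report` with raw and
#'   Holm-adjusted p-values (`p_adj >= p_raw` always) and significance at
#'   `alpha`.
#' @examples
#' comparison_report(c(0.01, 0.04, 0.03))$p_adj
#' @export
comparison_report <- function(comparisons, alpha = 0.05) {
  if (is.numeric(comparisons)) {
    p <- comparisons
    labels <- paste0("comparison_", seq_along(p))
  } else {
    p <- vapply(comparisons, `[[`, numeric(1), "p_value")
    labels <- vapply(comparisons, `[[`, character(1), "label")
  }
  adj <- p.adjust(p, method = "holm")
  structure(data.frame(label = labels, p_raw = p, p_adj = adj,
                       significant = adj < alpha),
            class = c("comparison_report", "data.frame"), alpha = alpha)
}

#' Validate model predictions against observations
#'
#' Root-mean-square error, ordinary least-squares regression of the
#' observations on the predictions (slope, intercept) and Pearson
#' correlation, as used to validate a simulated pressure-radius response
#' against bench measurements.
#'
#' @param predicted,observed numeric vectors of equal length, `n >= 3`.
#' @return list of class `model_validation` with `rmse`, `slope`,
#'   `intercept`, `r`, `p_slope`, `n`.
#' @examples
#' validate_model(1:10, 1:10)
#' @export
validate_model <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need n >= 3")
  fit <- lm(observed ~ predicted)
  s <- suppressWarnings(summary(fit)) # silence the perfect-fit notice
  r <- if (var(predicted) == 0 || var(observed) == 0) NA_real_
       else unname(stats::cor(predicted, observed))
  structure(list(rmse = sqrt(mean((predicted - observed)^2)),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r,
                 p_slope = unname(s$coefficients[2, 4]),
                 n = length(predicted)),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf(
    "Model validation (n = %d): RMSE %.4g, slope %.4g, intercept %.4g, r %.4g\n",
    x$n, x$rmse, x$slope, x$intercept, x$r))
  invisible(x)
}
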