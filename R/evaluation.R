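# Scoring of severity calls against a gold standard, and the intra-rater
# agreement statistic used for repeated continuous ACH readings.

#' Pair predicted measurements with a gold standard
#'
#' Joins two measurement-schema tables on `(image_id, tooth_id, site)` and
#' returns the severity records for [evaluate_classification()]. Sites
#' present in only one table are dropped (a site the pipeline could not
#' measure has no severity call to score). When each table covers exactly
#' one image the two `image_id` labels are treated as the same image even
#' if they differ (predictions and gold standard commonly carry different
#' identifiers for one radiograph); the gold label is kept.
#'
#' @param pred,gold measurement data frames (see [write_measurements()]).
#' @return data frame with columns `image_id`, `tooth_id`, `site`,
#'   `gold_severe`, `pred_severe`.
#' @export
severity_records <- function(pred, gold) {
  key <- c("image_id", "tooth_id", "site")
  p <- pred[c(key, "severe")]; names(p)[4] <- "pred_severe"
  g <- gold[c(key, "severe")]; names(g)[4] <- "gold_severe"
  if (length(unique(p$image_id)) == 1 && length(unique(g$image_id)) == 1)
    p$image_id <- g$image_id[1]
  out <- merge(g, p, by = key, sort = TRUE)
  out[c(key, "gold_severe", "pred_severe")]
}

#' Score severity classifications against the gold standard
#'
#' Pooled and per-image accuracy, plus severe-class sensitivity (the share
#' of gold-severe sites called severe) and specificity. Sensitivity is `NA`
#' when no gold-severe site exists, specificity likewise for the
#' non-severe class.
#'
#' @param records data frame with columns `image_id`, `tooth_id`, `site`,
#'   `gold_severe`, `pred_severe` (see [severity_records()]); keys must be
#'   unique.
#' @return an object of class `ach_eval_report`: `n_sites`,
#'   `accuracy_pct`, `sensitivity_severe_pct`, `specificity_pct`,
#'   `per_image` (data frame `image_id`, `n`, `accuracy_pct`).
#' @examples
#' rec <- data.frame(image_id = "bw1", tooth_id = 1:6, site = "left",
#'                   gold_severe = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
#'                   pred_severe = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
#' evaluate_classification(rec)  # 5/6 concordant: 83.3%
#' @export
evaluate_classification <- function(records) {
  need <- c("image_id", "tooth_id", "site", "gold_severe", "pred_severe")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_achr("records lack column(s): ", paste(miss, collapse = ", "),
              class = "achr_parse_error")
  if (nrow(records) == 0)
    stop_achr("no records to evaluate", class = "achr_domain_error")
  key <- paste(records$image_id, records$tooth_id, records$site)
  if (anyDuplicated(key))
    stop_achr("duplicate (image_id, tooth_id, site) keys in records",
              class = "achr_validation_error")
  ok <- records$pred_severe == records$gold_severe
  n <- nrow(records)
  sens <- if (any(records$gold_severe))
    100 * sum(ok & records$gold_severe) / sum(records$gold_severe) else NA_real_
  spec <- if (any(!records$gold_severe))
    100 * sum(ok & !records$gold_severe) / sum(!records$gold_severe) else NA_real_
  per <- aggregate(ok, by = list(image_id = records$image_id),
                   FUN = function(v) c(n = length(v), acc = 100 * mean(v)))
  per_image <- data.frame(image_id = per$image_id,
                          n = as.integer(per$x[, "n"]),
                          accuracy_pct = as.numeric(per$x[, "acc"]),
                          stringsAsFactors = FALSE)
  structure(list(n_sites = n, accuracy_pct = 100 * mean(ok),
                 sensitivity_severe_pct = sens, specificity_pct = spec,
                 per_image = per_image),
            class = "ach_eval_report")
}

# round half up to integer percent, the convention used for display
round_pct <- function(p) floor(p + 0.5)

#' @export
print.ach_eval_report <- function(x, ...) {
  cat(sprintf("severity classification on %d site(s): accuracy %g%% (%d%%)\n",
              x$n_sites, signif(x$accuracy_pct, 4), round_pct(x$accuracy_pct)))
  if (!is.na(x$sensitivity_severe_pct))
    cat(sprintf("  severe-class sensitivity %g%%, specificity %s%%\n",
                signif(x$sensitivity_severe_pct, 4),
                if (is.na(x$specificity_pct)) "NA"
                else signif(x$specificity_pct, 4)))
  for (i in seq_len(nrow(x$per_image)))
    cat(sprintf("  %s: n = %d, accuracy %g%%\n", x$per_image$image_id[i],
                x$per_image$n[i], signif(x$per_image$accuracy_pct[i], 4)))
  invisible(x)
}

#' Intraclass correlation for repeated measurements, ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (McGraw & Wong's ICC(A,1)) computed from the mean-squares decomposition
#' of the n x 2 ratings table:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 occasions. Absolute agreement (rather than consistency) is
#' the appropriate form for repeated readings by one rater: a constant
#' shift between the two occasions is penalized.
#'
#' @param ratings_1,ratings_2 numeric vectors of the same length
#'   (n >= 3), e.g. first and repeat ACH readings in mm of the same sites.
#' @return the ICC estimate (1 for perfect agreement; can be negative,
#'   and below -1 in adversarial tables, when disagreement exceeds chance).
#' @examples
#' r <- c(7.1, 5.2, 8.3, 4.4, 6.0)
#' intraclass_correlation(r, r)          # exactly 1
#' intraclass_correlation(r, r + 2)      # < 1: bias is penalized
#' @export
intraclass_correlation <- function(ratings_1, ratings_2) {
  if (length(ratings_1) != length(ratings_2))
    stop_achr("rating vectors must have equal length",
              class = "achr_domain_error")
  n <- length(ratings_1)
  if (n < 3) stop_achr("ICC needs at least 3 subjects",
                       class = "achr_domain_error")
  if (any(!is.finite(ratings_1)) || any(!is.finite(ratings_2)))
    stop_achr("ratings must be finite", class = "achr_domain_error")
  tab <- cbind(ratings_1, ratings_2)
  k <- 2
  grand <- mean(tab)
  if (sum((tab - grand)^2) == 0)
    stop_achr("zero total variance: ICC undefined for constant ratings",
              class = "achr_degenerate_error")
  row_m <- rowMeans(tab); col_m <- colMeans(tab)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((tab - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
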