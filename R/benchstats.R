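# Benchmark statistics: ROC and precision-recall curves, AUROC/AUPRC,
# optimal cutoffs (Youden's J), and the fragmentation-approach
# sensitivity / false-positive-rate summary.

#' ROC and PR analysis of a scored benchmark set
#'
#' Sweeps all observed score values as thresholds (predicting "positive" at
#' or above the threshold after orienting the metric so that higher is
#' better; ties are grouped at one threshold). AUROC is computed by the
#' trapezoid rule, AUPRC by step-wise interpolation (no linear
#' interpolation between PR points).
#'
#' @param values Numeric metric values.
#' @param labels Labels parallel to `values`; `"positive"` or `"random"`.
#' @param orientation `"higher_is_better"` (pLDDT-like metrics) or
#'   `"lower_is_better"` (iPAE).
#' @param metric_name Optional name stored on the result.
#' @return Object of class `roc_analysis`: list with `curve` (data frame of
#'   `threshold`, `tpr`, `fpr`, `precision`, thresholds on the original
#'   scale), `auroc`, `auprc`, `n_pos`, `n_neg`, `orientation`,
#'   `metric_name`.
#' @export
roc_auc <- function(values, labels,
                    orientation = c("higher_is_better", "lower_is_better"),
                    metric_name = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(length(values) == length(labels))
  if (any(!labels %in% c("positive", "random")))
    stop("labels must be 'positive' or 'random'")
  pos <- labels == "positive"
  if (!any(pos) || all(pos))
    stop("both positive and random labels are required")
  s <- if (orientation == "lower_is_better") -values else values

  th <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(s[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(s[!pos] >= t), numeric(1))
  prec <- vapply(th, function(t) {
    called <- s >= t
    sum(pos & called) / sum(called)
  }, numeric(1))

  fx <- c(0, fpr, 1); ty <- c(0, tpr, 1)
  auroc <- sum(diff(fx) * (utils::head(ty, -1) + utils::tail(ty, -1)) / 2)
  auprc <- sum(diff(c(0, tpr)) * prec)  # step-wise (recall increases with th)

  curve <- data.frame(
    threshold = if (orientation == "lower_is_better") -th else th,
    tpr = tpr, fpr = fpr, precision = prec)
  structure(
    list(curve = curve, auroc = auroc, auprc = auprc,
         n_pos = sum(pos), n_neg = sum(!pos), orientation = orientation,
         metric_name = metric_name,
         pr_interpolation = "step-wise"),
    class = "roc_analysis"
  )
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("roc_analysis%s: AUROC %.3f, AUPRC %.3f (%d positive, %d random, %s)\n",
              if (is.null(x$metric_name)) "" else paste0(" [", x$metric_name, "]"),
              x$auroc, x$auprc, x$n_pos, x$n_neg, x$orientation))
  invisible(x)
}

#' @export
plot.roc_analysis <- function(x, ...) {
  graphics::plot(c(0, x$curve$fpr, 1), c(0, x$curve$tpr, 1), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUROC %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Optimal threshold of a ROC curve
#'
#' Maximizes Youden's J = TPR - FPR over the swept thresholds; ties are
#' resolved towards the more stringent threshold.
#'
#' @param roc A `roc_analysis` from [roc_auc()].
#' @return List with `threshold` (original metric scale), `tpr`, `fpr` and
#'   `youden_j`.
#' @export
optimal_cutoff <- function(roc) {
  cv <- roc$curve
  j <- cv$tpr - cv$fpr
  best <- which(j == max(j))
  # curve rows are ordered from most to least stringent
  best <- best[1]
  list(threshold = cv$threshold[best], tpr = cv$tpr[best],
       fpr = cv$fpr[best], youden_j = j[best])
}

#' Per-PPI summary of the fragmentation approach
#'
#' Aggregates per-model confidence calls to the protein-pair level: a PPI is
#' "confident" when any of its fragment-pair models is called confident, and
#' "confident and accurate" when any confident model is also accurate (motif
#' RMSD at most 5 A, supplied via `accurate`). Sensitivity is the fraction
#' of positive PPIs with a confident accurate model; the false positive rate
#' is the fraction of random PPIs with at least one confident model.
#'
#' @param per_model Data frame with one row per model: columns `ppi_id`,
#'   `label` (`"positive"`/`"random"`), `confident` (logical) and optionally
#'   `accurate` (logical; `NA` allowed where no native evaluation exists).
#' @return List with `per_ppi` (data frame of per-PPI flags), `sensitivity`
#'   and `fpr` (`NA` when the respective label is absent).
#' @export
fragmentation_summary <- function(per_model) {
  stopifnot(all(c("ppi_id", "label", "confident") %in% names(per_model)))
  if (nrow(per_model) == 0L) stop("no models supplied")
  has_acc <- "accurate" %in% names(per_model)
  groups <- split(per_model, per_model$ppi_id)
  per_ppi <- do.call(rbind, lapply(groups, function(g) data.frame(
    ppi_id = g$ppi_id[1], label = g$label[1],
    any_confident = any(g$confident, na.rm = TRUE),
    any_confident_accurate = if (has_acc)
      any(g$confident & g$accurate, na.rm = TRUE) else NA,
    n_models = nrow(g), stringsAsFactors = FALSE)))
  rownames(per_ppi) <- NULL
  pos <- per_ppi$label == "positive"
  sensitivity <- if (any(pos) && has_acc)
    mean(per_ppi$any_confident_accurate[pos]) else NA_real_
  fpr <- if (any(!pos)) mean(per_ppi$any_confident[!pos]) else NA_real_
  list(per_ppi = per_ppi, sensitivity = sensitivity, fpr = fpr)
}
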