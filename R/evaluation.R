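# Evaluation protocol: confusion-based metrics, rank-based AUROC and
# step-integrated AUPRC, stratified repeated k-fold cross-validation,
# stratified train-test split, and Welch's t-test between result sets.

#' Confusion counts for binary predictions
#'
#' @param truth,pred equal-length 0/1 vectors
#' @return one-row tibble with `tp`, `fp`, `tn`, `fn`
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    vox_abort("validation", "truth and pred must have equal length")
  }
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1)) {
    vox_abort("validation", "labels must be 0 or 1")
  }
  tibble(tp = sum(truth == 1 & pred == 1),
         fp = sum(truth == 0 & pred == 1),
         tn = sum(truth == 0 & pred == 0),
         fn = sum(truth == 1 & pred == 0))
}

#' Performance metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, precision,
#' F-score and Matthews correlation coefficient:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A metric whose denominator is zero is reported as `NA` (undefined)
#' rather than coerced to 0; the names of undefined metrics are attached
#' as the `"undefined"` attribute.
#'
#' @param cc one-row tibble from [confusion_counts()]
#' @return one-row tibble of the six metrics
#' @export
metrics_from_confusion <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  total <- tp + fp + tn + fn
  if (total == 0) {
    vox_abort("validation", "confusion counts are all zero")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  f <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- tibble(
    accuracy = (tp + tn) / total,
    sensitivity = sens,
    specificity = safe_div(tn, tn + fp),
    precision = prec,
    f_score = f,
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
  attr(out, "undefined") <- names(out)[vapply(out, is.na, TRUE)]
  out
}

check_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    vox_abort("validation", "scores and labels must have equal length")
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    vox_abort("validation", "both classes must be present")
  }
  labels
}

#' Area under the ROC curve (rank form)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted half:
#' `AUROC = (sum of positive ranks - n_pos (n_pos + 1) / 2) /
#'  (n_pos n_neg)` using midranks.
#'
#' @param scores numeric scores, larger = more positive
#' @param labels 0/1 labels
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- check_scores(scores, labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step integral)
#'
#' Thresholds sweep the distinct score values from high to low; the curve
#' is integrated as `sum over threshold steps of
#' (recall_i - recall_(i-1)) * precision_i` (precision at the new recall
#' level), the usual step-wise estimator.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`
#' @export
auprc <- function(scores, labels) {
  labels <- check_scores(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep only the last index of each tied score block
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- tp[keep]
  fp <- fp[keep]
  recall <- tp / sum(labels == 1)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Metrics report for scored predictions
#'
#' Combines the confusion metrics at the 0.5 threshold with AUROC and
#' AUPRC of the scores.
#'
#' @param pred tibble with columns `label` (truth), `prob` and optionally
#'   `pred` (defaults to `prob > threshold`)
#' @param threshold decision threshold (default 0.5, strict)
#' @return one-row tibble with the eight performance measures
#' @export
evaluate_predictions <- function(pred, threshold = 0.5) {
  hard <- if ("pred" %in% names(pred)) {
    pred$pred
  } else {
    as.integer(pred$prob > threshold)
  }
  cc <- confusion_counts(pred$label, hard)
  dplyr::bind_cols(metrics_from_confusion(cc),
                   tibble(auroc = auroc(pred$prob, pred$label),
                          auprc = auprc(pred$prob, pred$label)))
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      vox_abort("stratification",
                sprintf("class %s has %d members, fewer than k = %d",
                        cl, length(idx), k))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified train-test split
#'
#' Disjoint, covering, per-class proportional split, deterministic per
#' seed.
#'
#' @param data tibble with a `label` column
#' @param test_fraction fraction held out (default 0.2)
#' @param seed RNG seed
#' @param stratified stratify on `label` (default `TRUE`)
#' @return list with `train` and `test` tibbles
#' @export
train_test_split <- function(data, test_fraction = 0.2, seed = 1,
                             stratified = TRUE) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    vox_abort("config", "`test_fraction` must be in (0, 1)")
  }
  n <- nrow(data)
  with_seed(seed, {
    test_idx <- if (stratified) {
      unlist(lapply(unique(data$label), function(cl) {
        idx <- which(data$label == cl)
        sample(idx, round(test_fraction * length(idx)))
      }))
    } else {
      sample.int(n, round(test_fraction * n))
    }
    list(train = data[setdiff(seq_len(n), test_idx), ],
         test = data[test_idx, ])
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `repeats` independent k-fold partitions (default 3 x 3-fold, i.e.
#' 9 fold evaluations). Within each repeat the folds are disjoint, cover
#' the data, and are stratified within one sample per class. The summary
#' reports the mean and sample (n-1) standard deviation of every metric
#' over all folds.
#'
#' @param data tibble with a `label` column (and whatever the trainer
#'   needs)
#' @param trainer function `trainer(train_data)` returning a prediction
#'   function `function(test_data) -> numeric scores in [0, 1]`
#' @param k folds per repeat (default 3)
#' @param repeats number of repeats (default 3)
#' @param seed RNG seed; fold assignment of repeat r uses a child seed
#' @param stratified stratify folds on `label` (default `TRUE`)
#' @return a `ppi_cv` object; [tidy()] gives the per-fold metrics,
#'   [glance()] the mean/sd summary
#' @export
repeated_kfold <- function(data, trainer, k = 3, repeats = 3, seed = 1,
                           stratified = TRUE) {
  if (nrow(data) < k) vox_abort("validation", "fewer samples than folds")
  if (length(unique(data$label)) < 2) {
    vox_abort("validation", "data must contain both classes")
  }
  rows <- list()
  assignments <- list()
  for (r in seq_len(repeats)) {
    fold <- with_seed(child_seed(seed, r), {
      if (stratified) {
        stratified_folds(data$label, k)
      } else {
        sample(rep_len(seq_len(k), nrow(data)))
      }
    })
    assignments[[r]] <- fold
    for (f in seq_len(k)) {
      train <- data[fold != f, ]
      test <- data[fold == f, ]
      predict_fn <- trainer(train)
      scores <- predict_fn(test)
      rep_metrics <- evaluate_predictions(
        tibble(label = test$label, prob = scores))
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble(`repeat` = r, fold = f,
                                n_test = nrow(test)), rep_metrics)
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  metric_cols <- setdiff(names(folds_tbl), c("repeat", "fold", "n_test"))
  summary <- tibble(
    metric = metric_cols,
    mean = unname(vapply(folds_tbl[metric_cols], mean, 1, na.rm = TRUE)),
    sd = unname(vapply(folds_tbl[metric_cols], sd, 1, na.rm = TRUE))
  )
  structure(list(folds = folds_tbl, summary = summary,
                 assignments = assignments, k = k, repeats = repeats,
                 seed = seed),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("<ppi_cv: %d-fold x %d repeats, %d evaluations>\n",
              x$k, x$repeats, nrow(x$folds)))
  print(x$summary)
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x a `ppi_cv`
#' @param ... unused
#' @return tibble with one row per fold evaluation
#' @method tidy ppi_cv
#' @export
tidy.ppi_cv <- function(x, ...) x$folds

#' Cross-validation summary (mean and sd per metric)
#' @param x a `ppi_cv`
#' @param ... unused
#' @return one-row tibble: `<metric>_mean` and `<metric>_sd` columns
#' @method glance ppi_cv
#' @export
glance.ppi_cv <- function(x, ...) {
  wide <- c(setNames(x$summary$mean, paste0(x$summary$metric, "_mean")),
            setNames(x$summary$sd, paste0(x$summary$metric, "_sd")))
  dplyr::bind_cols(tibble(k = x$k, repeats = x$repeats),
                   as_tibble(as.list(wide)))
}

#' Plot per-fold cross-validation metrics
#' @param object a `ppi_cv`
#' @param ... unused
#' @return a ggplot with one boxplot per metric over fold evaluations
#' @method autoplot ppi_cv
#' @export
autoplot.ppi_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds,
                            -c("repeat", "fold", "n_test"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$`repeat`)),
                        position = ggplot2::position_jitter(width = 0.1),
                        alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "value", colour = "repeat") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, with a significance flag at the 0.05
#' level.
#'
#' @param a,b numeric vectors (length >= 2 each; at least one with
#'   positive variance)
#' @param alpha significance level (default 0.05)
#' @return one-row tibble: `t`, `df`, `p_value`, `significant`
#' @export
welch_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    vox_abort("validation", "each sample needs at least 2 values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      vox_abort("undefined_statistic",
                "both samples constant and equal: t is undefined")
    }
    # separated point masses: the statistic degenerates to +-Inf
    return(tibble(t = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                  p_value = 0, significant = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, significant = ht$p.value < alpha)
}
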