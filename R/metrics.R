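#' Micro-aggregated multi-class confusion counts
#'
#' For each class `c` the one-vs-rest TP/TN/FP/FN are accumulated and summed
#' across all `K` classes (micro aggregation). For single-label predictions
#' this gives `TP + FN = n` and `TP + TN + FP + FN = n * K`.
#'
#' @param truth Integer class labels in `0:(K-1)`.
#' @param pred Predicted labels, same coding and length.
#' @param K Number of classes.
#' @return A `confusion_counts` object: list with integer `TP`, `TN`, `FP`,
#'   `FN` and `K`, `n`.
#' @export
aggregate_confusion <- function(truth, pred, K) {
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length", call. = FALSE)
  K <- as.integer(K)
  if (any(truth < 0 | truth >= K) || any(pred < 0 | pred >= K))
    stop("labels must lie in 0:(K-1)", call. = FALSE)
  n <- length(truth)
  TP <- TN <- FP <- FN <- 0L
  for (c in seq_len(K) - 1L) {
    tc <- truth == c
    pc <- pred == c
    TP <- TP + sum(tc & pc)
    FN <- FN + sum(tc & !pc)
    FP <- FP + sum(!tc & pc)
    TN <- TN + sum(!tc & !pc)
  }
  confusion_counts(TP, TN, FP, FN, K = K)
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN Non-negative counts (micro-aggregated over classes).
#' @param K Number of classes (optional, `NA` if unknown).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN, K = NA_integer_) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, K = K,
                 n = TP + FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d, K=%s)\n",
              x$TP, x$TN, x$FP, x$FN, x$n,
              ifelse(is.na(x$K), "?", x$K)))
  invisible(x)
}

safe_div <- function(num, den) if (den <= 0) NA_real_ else num / den

#' Rate metrics from confusion counts
#'
#' Standard one-number summaries from micro-aggregated TP/TN/FP/FN:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' NPV `TN/(TN+FN)`, the complements FNR/FDR/fallout, Youden index
#' `recall + specificity - 1`, Matthews correlation coefficient, F1,
#' F-beta, IoU (Jaccard) `TP/(TP+FP+FN)` and Dice `2TP/(2TP+FP+FN)`.
#' Accuracy is reported as micro recall `TP/(TP+FN)`, which for single-label
#' predictions equals the plain fraction of correct labels.
#'
#' Metrics whose denominator is zero are reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param counts A [confusion_counts] object.
#' @param beta F-beta weight (recall weighted `beta` times precision);
#'   default 2.
#' @return Named list of rates, all in `[0, 1]` (MCC in `[-1, 1]`).
#' @examples
#' cc <- confusion_counts(TP = 12360, TN = 37953, FP = 423, FN = 432, K = 4)
#' round(100 * derive_rate_metrics(cc)$precision, 2)  # 96.69
#' @export
derive_rate_metrics <- function(counts, beta = 2) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, TN + FP)
  npv <- safe_div(TN, TN + FN)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den <= 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  f1 <- if (anyNA(c(precision, recall)) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  fbeta <- if (anyNA(c(precision, recall))) NA_real_ else {
    den <- beta^2 * precision + recall
    if (den == 0) NA_real_
    else (1 + beta^2) * precision * recall / den
  }
  list(accuracy = recall,
       precision = precision,
       recall = recall,
       specificity = specificity,
       npv = npv,
       fnr = if (is.na(recall)) NA_real_ else 1 - recall,
       fdr = if (is.na(precision)) NA_real_ else 1 - precision,
       fallout = if (is.na(specificity)) NA_real_ else 1 - specificity,
       youden = recall + specificity - 1,
       mcc = mcc,
       f1 = f1,
       fbeta = fbeta,
       iou = safe_div(TP, TP + FP + FN),
       dice = safe_div(2 * TP, 2 * TP + FP + FN))
}

#' Probability-based loss and similarity metrics
#'
#' Computes the loss suite on predicted class-probability rows against
#' one-hot truth: categorical crossentropy, Kullback-Leibler divergence,
#' categorical hinge, hinge, squared hinge (hinge family on `{-1, 1}`
#' targets), Poisson, log-cosh, MAE, MSE, MSLE, RMSE (`sqrt(MSE)`) and
#' cosine similarity. All are means over samples; elementwise losses are
#' additionally averaged over classes.
#'
#' @param true_onehot `n x K` one-hot matrix (one 1 per row).
#' @param probs `n x K` matrix of finite predicted probabilities; rows must
#'   have positive sums.
#' @param eps Floor applied inside logarithms.
#' @return Named list of losses.
#' @export
probability_losses <- function(true_onehot, probs, eps = 1e-7) {
  y <- as.matrix(true_onehot); p <- as.matrix(probs)
  stopifnot(all(dim(y) == dim(p)))
  if (!all(is.finite(p)))
    stop("predicted probabilities must be finite", call. = FALSE)
  if (any(rowSums(p) <= 0))
    stop("probability rows must have positive sums", call. = FALSE)
  pc <- pmin(pmax(p, eps), 1)
  yhat <- 2 * y - 1                      # {-1, 1} targets for hinge family
  hinge_mat <- pmax(0, 1 - yhat * p)
  cat_hinge <- pmax(0, 1 + apply((1 - y) * p, 1, max) - rowSums(y * p))
  cosine <- rowSums(y * p) /
    pmax(sqrt(rowSums(y^2)) * sqrt(rowSums(p^2)), eps)
  list(categorical_crossentropy = mean(-rowSums(y * log(pc))),
       kld = mean(rowSums(ifelse(y > 0, y * log(pmax(y, eps) / pc), 0))),
       categorical_hinge = mean(cat_hinge),
       hinge = mean(hinge_mat),
       squared_hinge = mean(hinge_mat^2),
       poisson = mean(p - y * log(pc)),
       logcosh = mean(log(cosh(p - y))),
       mae = mean(abs(p - y)),
       mse = mean((p - y)^2),
       msle = mean((log1p(p) - log1p(y))^2),
       rmse = sqrt(mean((p - y)^2)),
       cosine_similarity = mean(cosine))
}

#' One-vs-rest macro-averaged AUC
#'
#' Per class, the ROC of the class-`c` probability column against the
#' binary indicator `truth == c` is integrated (trapezoidal rule, via
#' \pkg{pROC}); classes absent from `truth` are skipped. The macro average
#' over the remaining classes is returned.
#'
#' @param truth Integer labels in `0:(K-1)`.
#' @param probs `n x K` probability matrix.
#' @return Scalar AUC in `[0, 1]` (`NA` if no class is scoreable).
#' @export
macro_auc <- function(truth, probs) {
  K <- ncol(probs)
  aucs <- vapply(seq_len(K) - 1L, function(c) {
    resp <- as.integer(truth == c)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, probs[, c + 1L], quiet = TRUE,
                                   direction = "<")))
  }, 0)
  if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
}

#' Full metric report
#'
#' Combines [aggregate_confusion()] + [derive_rate_metrics()] on the argmax
#' predictions with [probability_losses()] and [macro_auc()] on the
#' probability rows.
#'
#' @param truth Integer labels in `0:(K-1)`.
#' @param probs `n x K` probability matrix.
#' @param beta F-beta weight, passed through.
#' @return A `metric_report`: named list of all rates and losses, plus the
#'   `confusion` counts.
#' @export
metric_report <- function(truth, probs, beta = 2) {
  K <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  counts <- aggregate_confusion(truth, pred, K)
  y <- matrix(0, nrow = length(truth), ncol = K)
  y[cbind(seq_along(truth), truth + 1L)] <- 1
  rep <- c(derive_rate_metrics(counts, beta = beta),
           probability_losses(y, probs),
           list(auc = macro_auc(truth, probs)))
  rep$confusion <- counts
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  accuracy %.4f | precision %.4f | recall %.4f | specificity %.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity))
  cat(sprintf("  F1 %.4f | MCC %.4f | Youden %.4f | AUC %s\n",
              x$f1, x$mcc, x$youden,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  cat(sprintf("  crossentropy %.4f | MSE %.4f | cosine %.4f\n",
              x$categorical_crossentropy, x$mse, x$cosine_similarity))
  invisible(x)
}

#' Serialize a metric report
#'
#' Writes the scalar metrics as JSON and/or a two-column CSV
#' (metric, value).
#'
#' @param report A [metric_report()] result (or any named list of scalars).
#' @param json_path,csv_path Output paths; `NULL` to skip either.
#' @return Invisibly, the named numeric vector written.
#' @export
write_metric_report <- function(report, json_path = NULL, csv_path = NULL) {
  scalars <- report[vapply(report, function(v)
    is.numeric(v) && length(v) == 1L, TRUE)]
  vec <- unlist(scalars)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(vec), json_path, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(data.frame(metric = names(vec), value = vec,
                                row.names = NULL),
                     csv_path, row.names = FALSE)
  invisible(vec)
}

#' Reference confusion counts for eight fine-tuned CNN backbones
#'
#' Returns the benchmark confusion counts shipped with the package
#' (`inst/extdata/pretrained_confusion_counts.csv`): micro-aggregated
#' TP/TN/FP/FN for eight pretrained CNN backbones fine-tuned on two
#' Alzheimer's MRI classification datasets (a four-class clinical-stage
#' dataset, `kaggle4`, and the three-class ADNI cohort, `adni`).
#'
#' @return Data frame with columns dataset, model, TP, TN, FP, FN, K.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "pretrained_confusion_counts.csv",
                      package = "gtotune", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute reference rate metrics and report discrepancies
#'
#' Recomputes precision, recall, specificity, NPV, Youden, MCC, FNR, FDR
#' and fallout from the shipped reference confusion counts and compares
#' each to the corresponding published cell
#' (`inst/extdata/pretrained_metric_cells.csv`), rounded to the published
#' number of digits. Cells that disagree (the published tables mix
#' count-derived values with streaming/thresholded variants for some
#' metrics) are flagged rather than silently accepted.
#'
#' @return Data frame with columns dataset, model, metric, printed,
#'   computed, rounded, digits, consistent.
#' @export
reference_metric_report <- function() {
  counts <- reference_confusion_counts()
  cells <- utils::read.csv(system.file("extdata",
                                       "pretrained_metric_cells.csv",
                                       package = "gtotune",
                                       mustWork = TRUE),
                           stringsAsFactors = FALSE)
  cells$computed <- NA_real_
  for (i in seq_len(nrow(cells))) {
    row <- counts[counts$dataset == cells$dataset[i] &
                    counts$model == cells$model[i], ]
    m <- derive_rate_metrics(confusion_counts(row$TP, row$TN, row$FP,
                                              row$FN, K = row$K))
    v <- m[[cells$metric[i]]]
    cells$computed[i] <- if (cells$scale[i] == "percent") 100 * v else v
  }
  cells$rounded <- round(cells$computed, cells$digits)
  cells$consistent <- abs(cells$rounded - cells$printed) < 1e-9
  cells
}
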