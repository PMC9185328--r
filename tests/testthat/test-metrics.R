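test_that("micro confusion aggregation matches the brute-force tables", {
  # perfect 3-class predictions
  cc <- aggregate_confusion(rep(0:2, c(4, 3, 3)), rep(0:2, c(4, 3, 3)), 3)
  expect_identical(c(cc$TP, cc$FN, cc$FP, cc$TN), c(10L, 0L, 0L, 20L))
  # all-wrong binary predictions
  cw <- aggregate_confusion(c(0, 0, 1, 1), c(1, 1, 0, 0), 2)
  expect_identical(c(cw$TP, cw$FN, cw$FP, cw$TN), c(0L, 4L, 4L, 0L))
  # random labels against an independent scalar-loop oracle
  set.seed(31)
  for (K in c(2L, 4L)) {
    truth <- sample(0:(K - 1), 200, replace = TRUE)
    pred <- sample(0:(K - 1), 200, replace = TRUE)
    got <- aggregate_confusion(truth, pred, K)
    ref <- oracle_confusion(truth, pred, K)
    expect_identical(got$TP, as.integer(ref$TP))
    expect_identical(got$TN, as.integer(ref$TN))
    expect_identical(got$FP, as.integer(ref$FP))
    expect_identical(got$FN, as.integer(ref$FN))
    expect_identical(got$TP + got$FN, 200L)
    expect_identical(got$TP + got$TN + got$FP + got$FN, 200L * K)
  }
  expect_error(aggregate_confusion(0:2, 0:1, 3), "length")
})

test_that("rate metrics reproduce the published MobileNet benchmark row", {
  cc <- confusion_counts(TP = 12360, TN = 37953, FP = 423, FN = 432, K = 4)
  m <- derive_rate_metrics(cc)
  expect_equal(round(100 * m$precision, 2), 96.69)
  expect_equal(round(100 * m$recall, 2), 96.62)
  expect_equal(round(100 * m$specificity, 2), 98.90)
  expect_equal(round(100 * m$youden, 2), 95.52)
  expect_equal(round(100 * m$mcc, 2), 95.54)
  expect_equal(round(m$fnr, 3), 0.034)
  expect_equal(round(m$fdr, 3), 0.033)
  expect_equal(round(m$fallout, 3), 0.011)
})

test_that("rate identities and degeneracies hold", {
  m1 <- derive_rate_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(m1$precision, 0.5)
  expect_equal(m1$recall, 0.5)
  expect_equal(m1$specificity, 0.5)
  expect_equal(m1$mcc, 0)
  set.seed(12)
  for (i in 1:50) {
    cc <- confusion_counts(sample(0:50, 1) + 1, sample(0:50, 1) + 1,
                           sample(0:50, 1), sample(0:50, 1))
    m <- derive_rate_metrics(cc)
    expect_equal(m$fnr, 1 - m$recall)
    expect_equal(m$fdr, 1 - m$precision)
    expect_equal(m$fallout, 1 - m$specificity)
    expect_equal(m$youden, m$recall + m$specificity - 1)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_equal(m$accuracy, m$recall)   # micro aggregation identity
  }
  # zero denominators surface as NA, never as 0
  und <- derive_rate_metrics(confusion_counts(0, 5, 0, 3))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$fdr))
})

test_that("probability losses match closed forms and the elementwise oracle", {
  K <- 4
  y <- diag(K)[c(1, 2, 3, 4, 1, 3), ]
  # perfect predictions
  pl <- probability_losses(y, y)
  expect_equal(pl$categorical_crossentropy, 0, tolerance = 1e-6)
  expect_equal(pl$mse, 0)
  expect_equal(pl$cosine_similarity, 1)
  # uniform predictions: crossentropy ln K
  pu <- probability_losses(y, matrix(1 / K, nrow(y), K))
  expect_equal(pu$categorical_crossentropy, log(K), tolerance = 1e-6)
  expect_equal(pu$kld, log(K), tolerance = 1e-6)
  # random batch against the brute-force loop
  set.seed(44)
  p <- matrix(rexp(6 * K), 6, K); p <- p / rowSums(p)
  got <- probability_losses(y, p)
  ref <- oracle_losses(y, p)
  for (nm in names(ref)) expect_equal(got[[nm]], ref[[nm]],
                                      tolerance = 1e-12, label = nm)
  expect_error(probability_losses(y, y * 0), "positive")
})

test_that("macro AUC agrees with the rank-statistic oracle", {
  set.seed(5)
  truth <- sample(0:2, 60, replace = TRUE)
  p <- matrix(rexp(60 * 3), 60, 3); p <- p / rowSums(p)
  got <- macro_auc(truth, p)
  ref <- mean(vapply(0:2, function(c)
    oracle_auc_binary(as.integer(truth == c), p[, c + 1]), 0))
  expect_equal(got, ref, tolerance = 1e-12)
  # perfect separability
  y <- c(rep(0, 5), rep(1, 5))
  ps <- cbind(c(rep(0.9, 5), rep(0.1, 5)), c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(macro_auc(y, ps), 1)
})

test_that("published reference cells are reproduced where consistent", {
  rep <- reference_metric_report()
  # these metrics are count-consistent in every model column of both tables
  always <- c("recall", "specificity", "youden", "fnr", "fallout")
  expect_true(all(rep$consistent[rep$metric %in% always]))
  # the strongest model row of the four-class table reproduces fully
  mob <- rep[rep$dataset == "kaggle4" & rep$model == "MobileNet" &
               rep$metric != "npv", ]
  expect_true(all(mob$consistent))
  # inconsistent cells are flagged, not silently accepted: the three-class
  # Xception MCC cell (printed equal to its NPV) must appear in the
  # discrepancy listing
  xc <- rep[rep$dataset == "adni" & rep$model == "Xception" &
              rep$metric == "mcc", ]
  expect_false(xc$consistent)
  expect_equal(round(xc$computed, 2), 94.37)
})

test_that("metric_report ties counts, rates, losses and AUC together", {
  set.seed(9)
  truth <- sample(0:2, 90, replace = TRUE)
  p <- matrix(rexp(90 * 3), 90, 3); p <- p / rowSums(p)
  rep <- metric_report(truth, p)
  pred <- max.col(p, ties.method = "first") - 1L
  expect_equal(rep$accuracy, mean(pred == truth))
  expect_identical(rep$confusion$n, 90L)
  expect_true(rep$auc > 0 && rep$auc < 1)
  vec <- write_metric_report(rep,
                             json_path = withr::local_tempfile(fileext = ".json"),
                             csv_path = withr::local_tempfile(fileext = ".csv"))
  expect_true(all(c("accuracy", "mcc", "rmse", "auc") %in% names(vec)))
})
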