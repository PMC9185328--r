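test_that("classifier assembly follows the decoded configuration", {
  sp <- build_default_space()
  cfg <- map_solution(rep(0.5, 16), sp)
  tc <- train_config(seed = 1)
  # learn ratio 100: all backbone layers trainable
  cfg100 <- cfg; cfg100$tl_learn_ratio <- 100L
  m <- preserve_rng(1, build_classifier(backbone_spec(), cfg100, K = 3, tc))
  expect_true(all(m$trainable))
  # learn ratio 1: minimal count, at least one backbone layer + the head
  cfg1 <- cfg; cfg1$tl_learn_ratio <- 1L
  m1 <- preserve_rng(1, build_classifier(backbone_spec(), cfg1, K = 3, tc))
  expect_identical(m1$trainable, c(FALSE, TRUE, TRUE))
  # softmax head emits K probabilities summing to one
  X <- matrix(runif(5 * m1$feature_dim), 5)
  probs <- predict(m1, X)
  expect_identical(dim(probs), c(5L, 3L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-12)
  # unknown names error cleanly
  expect_error(backbone_spec("ResNet50"), "unknown backbone")
  expect_error(build_classifier(backbone_spec("VGG16", "imagenet"), cfg, 3,
                                tc), "toy_cnn")
  cfg_bad <- cfg; cfg_bad$optimizer <- "nope"
  mb <- preserve_rng(1, build_classifier(backbone_spec(), cfg_bad, 3, tc))
  expect_error(train_classifier(mb, X, rep(0:2, length.out = 5), 1),
               "unknown optimizer")
})

test_that("every searched loss and optimizer trains without diverging", {
  sp <- build_default_space()
  b <- make_test_bundle(K = 2, n_per_class = 12, seed = 3)
  tc <- train_config(epochs = 1, seed = 2)
  for (loss in sp$specs$loss$domain) {
    for (opt in c("sgd", "adam", "ftrl", "adadelta")) {
      cfg <- map_solution(rep(0.6, 16), sp)
      cfg$loss <- loss; cfg$optimizer <- opt
      m <- preserve_rng(2, build_classifier(backbone_spec(), cfg, 2, tc))
      feats <- t(vapply(b$images, gtotune:::pool_features, numeric(64)))
      m <- preserve_rng(2,
        train_classifier(m, feats, b$labels, 1))
      expect_false(m$diverged, label = paste(loss, opt))
      expect_true(all(is.finite(predict(m, feats))),
                  label = paste(loss, opt))
    }
  }
  # the remaining optimizer rules at least take finite steps
  feats <- t(vapply(b$images, gtotune:::pool_features, numeric(64)))
  for (opt in sp$specs$optimizer$domain) {
    cfg <- map_solution(rep(0.4, 16), sp)
    cfg$optimizer <- opt
    m <- preserve_rng(4, build_classifier(backbone_spec(), cfg, 2, tc))
    m <- preserve_rng(4, train_classifier(m, feats, b$labels, 1))
    expect_false(m$diverged, label = opt)
  }
})

test_that("fitness is deterministic and beats chance on separable data", {
  b <- make_test_bundle(K = 2, n_per_class = 25, seed = 8)
  tc <- train_config(epochs = 5, seed = 5)
  set.seed(91); sol <- runif(16)
  r1 <- evaluate_fitness(sol, b, train_cfg = tc)
  r2 <- evaluate_fitness(sol, b, train_cfg = tc)
  expect_identical(r1$fitness, r2$fitness)
  expect_identical(r1$report$accuracy, r2$report$accuracy)
  # two-class phantom data is nearly separable: far better than chance
  expect_lt(r1$fitness, 0.5)
  expect_s3_class(r1$config, "hp_config")
  expect_s3_class(r1$confusion, "confusion_counts")
  expect_true(is.finite(r1$loss_value))
})

test_that("fitness evaluation does not perturb the caller's RNG stream", {
  b <- make_test_bundle(K = 2, n_per_class = 10, seed = 4)
  tc <- train_config(epochs = 1, seed = 3)
  set.seed(55); before <- runif(3)
  set.seed(55)
  invisible(evaluate_fitness(rep(0.3, 16), b, train_cfg = tc))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("augmentation on/off both yield valid results, differing only in DA", {
  b <- make_test_bundle(K = 2, n_per_class = 10, seed = 14)
  tc <- train_config(epochs = 1, seed = 7)
  sol_on <- rep(0.4, 16); sol_on[7] <- 0.2    # decodes to augmentation on
  sol_off <- sol_on; sol_off[7] <- 0.8        # decodes to augmentation off
  r_on <- evaluate_fitness(sol_on, b, train_cfg = tc)
  r_off <- evaluate_fitness(sol_off, b, train_cfg = tc)
  expect_true(r_on$config$augmentation_active)
  expect_false(r_off$config$augmentation_active)
  expect_true(is.finite(r_on$fitness) && is.finite(r_off$fitness))
  same_fields <- setdiff(names(r_on$config),
                         c("apply_augmentation", "augmentation_active"))
  expect_identical(unclass(r_on$config)[same_fields],
                   unclass(r_off$config)[same_fields])
})

test_that("a perfectly learnable dataset drives fitness toward zero", {
  # widely separated two-class data, evaluated on the full set
  b <- make_test_bundle(K = 2, n_per_class = 30, seed = 19)
  tc <- train_config(epochs = 8, seed = 11)
  sol <- rep(0, 16); sol[7] <- 0.9   # crossentropy + adam, augmentation off
  sol[4] <- 1                        # all layers trainable
  r <- evaluate_fitness(sol, b, train_cfg = tc)
  expect_lt(r$fitness, 0.1)
})

test_that("run ledger lines serialize solution, config and fitness", {
  b <- make_test_bundle(K = 2, n_per_class = 10, seed = 23)
  tc <- train_config(epochs = 1, seed = 2)
  r <- evaluate_fitness(rep(0.5, 16), b, train_cfg = tc)
  path <- withr::local_tempfile(fileext = ".jsonl")
  append_run_ledger(r, rep(0.5, 16), path)
  append_run_ledger(r, rep(0.5, 16), path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_length(rec$solution, 16L)
  expect_equal(rec$fitness, r$fitness)
  expect_identical(rec$config$loss, r$config$loss)
})
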