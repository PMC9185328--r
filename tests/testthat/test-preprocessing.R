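test_that("the four scaling techniques match their definitions", {
  expect_equal(scale_image(c(0, 2, 4), "normalize"), c(0, 0.5, 1))
  expect_equal(scale_image(c(2, 4), "minmax"), c(0, 1))
  expect_equal(scale_image(c(0, 2, 4), "maxabs"), c(0, 0.5, 1))
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  st <- scale_image(img, "standardize")
  expect_lt(abs(mean(st)), 1e-9)
  expect_lt(abs(sd(as.vector(st)) - 1), 1e-9)
  nm <- scale_image(img, "normalize")
  expect_equal(max(nm), 1, tolerance = 1e-12)
  mm <- scale_image(img, "minmax")
  expect_equal(range(mm), c(0, 1), tolerance = 1e-12)
  ma <- scale_image(img - 0.5, "maxabs")       # signed input
  expect_equal(ma, (img - 0.5) / abs(max(img - 0.5)))
  # degenerate denominators are explicit errors, not silent zeros
  expect_error(scale_image(matrix(0.5, 3, 3), "standardize"), "constant")
  expect_error(scale_image(matrix(0, 3, 3), "normalize"), "zero")
  expect_error(scale_image(matrix(1, 2, 2), "minmax"), "constant")
})

test_that("bicubic resize produces the 128x128x3 input and keeps constants", {
  out <- resize_to_input(matrix(0.5, 200, 100))
  expect_identical(dim(out), c(128L, 128L, 3L))
  expect_equal(out, array(0.5, dim(out)), tolerance = 1e-12)
  g <- resize_to_input(matrix(runif(256 * 256), 256, 256))
  expect_identical(dim(g), c(128L, 128L, 3L))
  expect_identical(g[, , 1], g[, , 2])  # grayscale replicated across channels
  rgb <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_identical(dim(resize_to_input(rgb)), c(128L, 128L, 3L))
  # a monotone ramp stays monotone and inside its original range
  ramp <- matrix(seq(0, 1, length.out = 64), 64, 64)
  down <- resize_to_input(ramp, size = c(32, 32))
  expect_true(all(diff(down[, 1, 1]) > 0))
  expect_true(all(down >= 0 & down <= 1))
  expect_error(resize_to_input(numeric(0)), "empty")
})

test_that("SNR is mean over sd with an infinite constant-image limit", {
  expect_identical(compute_snr(matrix(0.7, 10, 10)), Inf)
  x <- c(0.15, 2.15)  # mean 1.15, sd sqrt(2)
  expect_equal(compute_snr(x), 1.15 / sd(x))
  img <- matrix(c(1, 1.3, 1, 1.3), 2, 2)
  expect_equal(compute_snr(img), mean(img) / sd(as.vector(img)))
})

test_that("SNR cleaning keeps exactly the threshold-passing images", {
  gen <- generate_brain_dataset(synthetic_spec(K = 4, n_per_class = 25,
                                               image_size = c(32, 32),
                                               noisy_fraction = 0.1,
                                               seed = 17))
  cl <- clean_dataset(gen$bundle, threshold = 1.15)
  expect_identical(cl$removed, sum(gen$manifest$noisy))
  expect_identical(which(cl$snr < 1.15), which(gen$manifest$noisy))
  # order preserved and idempotent
  expect_identical(cl$bundle$labels,
                   gen$bundle$labels[!gen$manifest$noisy])
  cl2 <- clean_dataset(cl$bundle, threshold = 1.15)
  expect_identical(cl2$removed, 0L)
  expect_identical(cl2$bundle$images, cl$bundle$images)
  # vacuous threshold keeps everything; constant images always pass
  expect_identical(clean_dataset(gen$bundle, threshold = 0)$removed, 0L)
  const <- image_bundle(list(matrix(0.2, 8, 8), matrix(0.9, 8, 8)),
                        c(0L, 1L), c("a", "b"))
  expect_identical(clean_dataset(const)$removed, 0L)
})

test_that("category encoding assigns consecutive codes in given order", {
  expect_identical(encode_categories(c("NC", "MCI", "AD")),
                   c(NC = 0L, MCI = 1L, AD = 2L))
  expect_identical(encode_categories("only"), c(only = 0L))
  expect_identical(unname(encode_categories(letters[1:4])), 0:3)
  expect_error(encode_categories(c("a", "a")), "unique")
})

test_that("stratified split partitions with the configured shares", {
  gen <- generate_brain_dataset(synthetic_spec(K = 4, n_per_class = 100,
                                               image_size = c(16, 16),
                                               noisy_fraction = 0, seed = 2))
  b <- split_dataset(gen$bundle, seed = 10)
  expect_true(all(b$split %in% c("train", "validation", "test")))
  expect_identical(sum(b$split == "test"), 60L)  # 15 per class x 4
  per_class_test <- table(b$labels[b$split == "test"])
  expect_true(all(per_class_test == 15))
  b2 <- split_dataset(gen$bundle, seed = 10)
  expect_identical(b$split, b2$split)
  # unbalanced classes stay within one image of the target share
  ub <- image_bundle(rep(list(matrix(runif(16), 4, 4)), 37 + 61),
                     c(rep(0L, 37), rep(1L, 61)), c("a", "b"))
  sp <- split_dataset(ub, seed = 3)
  for (c in 0:1) {
    n_c <- sum(ub$labels == c)
    n_t <- sum(ub$labels == c & sp$split == "test")
    expect_lte(abs(n_t - 0.15 * n_c), 1)
  }
  tiny <- image_bundle(list(matrix(1:4 / 4, 2, 2), matrix(1:4 / 8, 2, 2)),
                       c(0L, 0L), "solo")
  expect_error(split_dataset(tiny), "at least 3")
})

test_that("augmenter honours identity configs and samples within bounds", {
  sp <- build_default_space()
  sol <- rep(0, 16)
  # element 7 in (0.5, 1] decodes augmentation off -> identity transform
  sol_off <- sol; sol_off[7] <- 0.9
  expect_identical(build_augmenter(map_solution(sol_off, sp)), identity)
  # augmentation on, all ranges zero, flips off, brightness [1,1]
  cfg <- map_solution(sol, sp)
  cfg$horizontal_flip <- FALSE; cfg$vertical_flip <- FALSE
  cfg$brightness_range <- c(1, 1)
  aug <- build_augmenter(cfg)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(aug(img), img)
  # rotation range 13: 1000 sampled angles stay inside [-13, 13]
  cfg13 <- cfg; cfg13$rotation_deg <- 13L
  angles <- preserve_rng(77, replicate(1000, gtotune:::sample_aug_params(cfg13)$angle))
  expect_true(all(abs(angles) <= 13))
  expect_gt(max(abs(angles)), 10)  # actually spans the range
  # brightness pair honoured
  cfgb <- cfg; cfgb$brightness_range <- c(0.54, 0.8)
  brs <- preserve_rng(78, replicate(500, gtotune:::sample_aug_params(cfgb)$brightness))
  expect_true(all(brs >= 0.54 & brs <= 0.8))
  # a geometric transform actually changes pixels but keeps the range
  cfgr <- cfg; cfgr$rotation_deg <- 20L; cfgr$zoom <- 0.2
  out <- preserve_rng(79, build_augmenter(cfgr)(img))
  expect_false(identical(out, img))
  expect_true(all(out >= -1e-9 & out <= 1 + 1e-9))
})

test_that("balanced epochs oversample minorities to the majority count", {
  labels <- c(rep(0L, 50), rep(1L, 100))
  plan <- preserve_rng(5, balanced_epoch_indices(labels))
  expect_identical(nrow(plan), 200L)
  expect_true(all(table(labels[plan$index]) == 100))
  # originals appear exactly once unaugmented
  expect_identical(sort(plan$index[!plan$augmented]), 1:150)
  expect_true(all(labels[plan$index[plan$augmented]] == 0L))
})
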