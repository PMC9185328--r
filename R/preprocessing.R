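#' Image dataset bundle
#'
#' The package's in-memory container for a class-labelled image set:
#' a list of `H x W` (grayscale) or `H x W x 3` numeric arrays with values
#' conventionally in `[0, 1]`, integer class codes in `0:(K-1)`, the ordered
#' class names, and an optional per-image split tag.
#'
#' @param images List of numeric arrays (`H x W` or `H x W x 3`).
#' @param labels Integer class codes in `0:(K-1)`, one per image.
#' @param class_names Ordered character vector of length `K`.
#' @param split Optional character vector of tags in
#'   `c("train", "validation", "test")`, one per image.
#' @return An `image_bundle` object.
#' @export
image_bundle <- function(images, labels, class_names, split = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(images) == length(labels),
            all(labels >= 0L), all(labels < length(class_names)),
            !anyDuplicated(class_names))
  if (!is.null(split)) {
    stopifnot(length(split) == length(images),
              all(split %in% c("train", "validation", "test")))
  }
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names), split = split),
            class = "image_bundle")
}

#' @export
print.image_bundle <- function(x, ...) {
  cat(sprintf("<image_bundle> %d images, %d classes (%s)\n",
              length(x$images), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  if (!is.null(x$split)) {
    tb <- table(factor(x$split, c("train", "validation", "test")))
    cat(sprintf("  split: train %d / validation %d / test %d\n",
                tb[1], tb[2], tb[3]))
  }
  invisible(x)
}

#' Image scaling techniques
#'
#' Rescales pixel intensities with one of four techniques:
#' `"normalize"` divides by the maximum, `X / max(X)`;
#' `"standardize"` centers and scales, `(X - mean) / sd`;
#' `"minmax"` maps the observed range onto `[0, 1]`,
#' `(X - min) / (max - min)`; and
#' `"maxabs"` divides by the largest absolute value, `X / |max(X)|`
#' (identical to `"normalize"` for non-negative images).
#'
#' @param image Numeric array (any shape), finite, non-empty.
#' @param technique One of `"normalize"`, `"standardize"`, `"minmax"`,
#'   `"maxabs"`.
#' @return The scaled array, same shape.
#' @section Degenerate inputs: a zero denominator (constant image for
#'   `standardize`/`minmax`, all-zero image for `normalize`/`maxabs`)
#'   raises an error rather than returning NaNs.
#' @examples
#' scale_image(c(0, 2, 4), "normalize")  # 0, 0.5, 1
#' scale_image(c(2, 4), "minmax")        # 0, 1
#' @export
scale_image <- function(image,
                        technique = c("normalize", "standardize", "minmax",
                                      "maxabs")) {
  technique <- match.arg(technique)
  x <- image
  if (length(x) == 0L || !all(is.finite(x)))
    stop("image must be non-empty and finite", call. = FALSE)
  out <- switch(technique,
    normalize = {
      m <- max(x)
      if (m == 0) stop("normalize: max(X) is zero", call. = FALSE)
      x / m
    },
    standardize = {
      s <- stats::sd(as.vector(x))
      if (s == 0) stop("standardize: constant image (sd = 0)", call. = FALSE)
      (x - mean(x)) / s
    },
    minmax = {
      r <- range(x)
      if (r[1] == r[2]) stop("minmax: constant image", call. = FALSE)
      (x - r[1]) / (r[2] - r[1])
    },
    maxabs = {
      m <- abs(max(x))
      if (m == 0) stop("maxabs: |max(X)| is zero", call. = FALSE)
      x / m
    })
  out
}

# Keys bicubic kernel, a = -0.5 (the conventional bicubic resampler).
cubic_kernel <- function(s) {
  s <- abs(s)
  a <- -0.5
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# Separable bicubic resampling of a single channel to out_h x out_w,
# with edge clamping; exact for constant images (kernel weights sum to 1).
resize_channel_bicubic <- function(ch, out_h, out_w) {
  in_h <- nrow(ch); in_w <- ncol(ch)
  resample_axis <- function(mat, n_out, n_in) {
    # maps output pixel centers onto input coordinates (align-centers)
    scale <- n_in / n_out
    src <- (seq_len(n_out) - 0.5) * scale + 0.5
    base <- floor(src - 2)
    W <- matrix(0, nrow = n_out, ncol = n_in)
    for (k in 1:4) {
      idx <- base + k
      w <- cubic_kernel(src - idx)
      idx <- pmin(pmax(idx, 1), n_in)
      for (i in seq_len(n_out)) W[i, idx[i]] <- W[i, idx[i]] + w[i]
    }
    W <- W / rowSums(W)
    W %*% mat
  }
  out <- resample_axis(ch, out_h, in_h)
  t(resample_axis(t(out), out_w, in_w))
}

#' Resize an image to the classifier input shape
#'
#' Bicubic resampling (Keys kernel, `a = -0.5`) to `size[1] x size[2]`,
#' returned in RGB mode (`H x W x 3`); grayscale inputs are replicated
#' across the three channels. Constant-valued images resize to the same
#' constant.
#'
#' @param image `H x W` or `H x W x C` numeric array, `C` in `{1, 3}`.
#' @param size Output height and width; default `c(128, 128)`.
#' @return `size[1] x size[2] x 3` array.
#' @export
resize_to_input <- function(image, size = c(128L, 128L)) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  dm <- dim(image)
  if (is.null(dm) || length(dm) < 2L)
    stop("image must be a 2-D or 3-D array", call. = FALSE)
  chans <- if (length(dm) == 2L) list(image)
           else lapply(seq_len(dm[3]), function(k) image[, , k])
  if (!length(chans) %in% c(1L, 3L))
    stop("images must have 1 or 3 channels", call. = FALSE)
  resized <- lapply(chans, resize_channel_bicubic,
                    out_h = size[1], out_w = size[2])
  if (length(resized) == 1L) resized <- resized[c(1, 1, 1)]
  array(unlist(resized), dim = c(size[1], size[2], 3L))
}

#' Per-image signal-to-noise ratio
#'
#' `SNR = mean(pixels) / sd(pixels)`, the conventional single-number
#' imaging SNR. A constant image (zero standard deviation) has no noise and
#' returns `+Inf`.
#'
#' @param image Numeric array.
#' @return Scalar SNR.
#' @export
compute_snr <- function(image) {
  s <- stats::sd(as.vector(image))
  if (s == 0) return(Inf)
  mean(image) / s
}

#' Remove noisy images by SNR threshold
#'
#' Keeps exactly the images whose [compute_snr()] is at or above
#' `threshold` (default 1.15), preserving order. The operation is
#' idempotent.
#'
#' @param bundle An [image_bundle].
#' @param threshold SNR threshold; images with `SNR < threshold` are
#'   removed.
#' @return List with `bundle` (the retained images), `removed` (count) and
#'   `snr` (the per-image SNR of the input bundle).
#' @export
clean_dataset <- function(bundle, threshold = 1.15) {
  stopifnot(inherits(bundle, "image_bundle"))
  snr <- vapply(bundle$images, compute_snr, 0)
  keep <- snr >= threshold
  if (!any(keep))
    warning("all images fall below the SNR threshold; result is empty")
  out <- image_bundle(bundle$images[keep], bundle$labels[keep],
                      bundle$class_names,
                      split = if (is.null(bundle$split)) NULL
                              else bundle$split[keep])
  list(bundle = out, removed = sum(!keep), snr = snr)
}

#' Encode class names as consecutive integer codes
#'
#' @param class_names Unique class names, in the order that defines the
#'   coding (first name gets 0).
#' @return Named integer vector mapping name to code `0:(K-1)`.
#' @examples
#' encode_categories(c("NC", "MCI", "AD"))  # NC=0, MCI=1, AD=2
#' @export
encode_categories <- function(class_names) {
  if (anyDuplicated(class_names))
    stop("class names must be unique", call. = FALSE)
  stats::setNames(seq_along(class_names) - 1L, class_names)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class (seeded) and assigns `round(n_c *
#' test_fraction)` images per class to the test set (default 15%, so the
#' per-class test share is within one image of the target), then carves the
#' validation set out of the remaining training share the same way.
#'
#' @param bundle An [image_bundle].
#' @param test_fraction Fraction per class assigned to test; default 0.15.
#' @param validation_fraction Fraction of the *training share* assigned to
#'   validation; default 0.10.
#' @param seed Integer seed for the shuffle.
#' @return The bundle with its `split` field set.
#' @export
split_dataset <- function(bundle, test_fraction = 0.15,
                          validation_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(bundle, "image_bundle"),
            test_fraction > 0, test_fraction < 1,
            validation_fraction >= 0, validation_fraction < 1)
  split <- character(length(bundle$images))
  preserve_rng(seed, {
    for (c in seq_along(bundle$class_names) - 1L) {
      idx <- which(bundle$labels == c)
      if (length(idx) < 3L)
        stop(sprintf("class '%s' has %d images; at least 3 required to split",
                     bundle$class_names[c + 1L], length(idx)), call. = FALSE)
      idx <- sample(idx)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test_idx <- idx[seq_len(n_test)]
      rest <- idx[-seq_len(n_test)]
      n_val <- round(length(rest) * validation_fraction)
      val_idx <- if (n_val > 0) rest[seq_len(n_val)] else integer(0)
      train_idx <- setdiff(rest, val_idx)
      split[test_idx] <- "test"
      split[val_idx] <- "validation"
      split[train_idx] <- "train"
    }
  })
  bundle$split <- split
  bundle
}

# Draws one set of augmentation parameters from the caller's RNG stream:
# angle uniform in +/- rotation_deg, shifts/shear uniform in +/- their
# configured fractions, zoom factor uniform in [1 - zoom, 1 + zoom],
# Bernoulli(1/2) flips when enabled, brightness uniform in the configured
# interval. Zero-width ranges draw nothing and stay exactly inert.
sample_aug_params <- function(config) {
  list(
    angle = if (config$rotation_deg > 0)
      stats::runif(1, -config$rotation_deg, config$rotation_deg) else 0,
    width_shift = if (config$width_shift > 0)
      stats::runif(1, -config$width_shift, config$width_shift) else 0,
    height_shift = if (config$height_shift > 0)
      stats::runif(1, -config$height_shift, config$height_shift) else 0,
    shear = if (config$shear > 0)
      stats::runif(1, -config$shear, config$shear) else 0,
    zoom = if (config$zoom > 0)
      stats::runif(1, 1 - config$zoom, 1 + config$zoom) else 1,
    flip_h = isTRUE(config$horizontal_flip) && stats::runif(1) < 0.5,
    flip_v = isTRUE(config$vertical_flip) && stats::runif(1) < 0.5,
    brightness = if (config$brightness_range[1] == config$brightness_range[2])
      config$brightness_range[1]
    else stats::runif(1, config$brightness_range[1],
                      config$brightness_range[2]))
}

# 2-D affine warp of one channel (bilinear sampling) via EBImage.
warp_channel <- function(ch, m) {
  img <- EBImage::Image(t(ch))          # EBImage is column-major (x, y)
  out <- EBImage::affine(img, m, filter = "bilinear",
                         output.dim = rev(dim(ch)), bg.col = 0)
  t(EBImage::imageData(out))
}

apply_affine <- function(image, m) {
  dm <- dim(image)
  if (length(dm) == 2L) return(warp_channel(image, m))
  out <- image
  for (k in seq_len(dm[3])) out[, , k] <- warp_channel(image[, , k], m)
  out
}

#' Build a seeded data-augmentation transform
#'
#' Returns `function(image)` applying, per call with freshly sampled
#' parameters: rotation by an angle uniform in `[-rotation_deg,
#' rotation_deg]`, width/height shifts uniform in plus or minus the
#' configured fraction of the image size, shear and zoom (factor uniform in
#' `[1 - zoom, 1 + zoom]`) as a single center-anchored affine warp with
#' bilinear sampling; horizontal/vertical flips with probability 1/2 when
#' the corresponding flag is on; and a multiplicative brightness factor
#' uniform in the configured interval, with the result clipped to `[0, 1]`.
#'
#' When every sampled parameter is inert (zero angle and shifts, unit zoom
#' and brightness, no flip) the input is returned pixel-identical. Called
#' with augmentation decoded off, the identity transform is returned.
#'
#' The transform consumes the caller's RNG stream; seed around it (e.g.
#' with [preserve_rng()]) for reproducible draws.
#'
#' @param config An `hp_config` from [map_solution()].
#' @return `function(image) -> image`.
#' @export
build_augmenter <- function(config) {
  stopifnot(inherits(config, "hp_config"))
  if (!config$augmentation_active) return(identity)
  force(config)
  function(image) {
    dm <- dim(image)
    h <- dm[1]; w <- dm[2]
    par <- sample_aug_params(config)
    angle <- par$angle
    dx <- par$width_shift * w
    dy <- par$height_shift * h
    sh <- par$shear
    zm <- par$zoom
    flip_h <- par$flip_h
    flip_v <- par$flip_v
    bright <- par$brightness

    out <- image
    if (angle != 0 || dx != 0 || dy != 0 || sh != 0 || zm != 1) {
      th <- angle * pi / 180
      # center-anchored rotation * shear * zoom, then shift, in EBImage's
      # (x, y) convention: p' = cbind(p, 1) %*% m with m a 3 x 2 matrix
      A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) %*%
        matrix(c(1, sh, 0, 1), 2, 2) %*% diag(c(zm, zm))
      cx <- w / 2; cy <- h / 2
      off <- c(cx, cy) - A %*% c(cx, cy) + c(dx, dy)
      m <- rbind(t(A), as.vector(off))
      out <- apply_affine(out, m)
    }
    if (flip_h) out <- if (length(dm) == 2L) out[, w:1] else out[, w:1, ]
    if (flip_v) out <- if (length(dm) == 2L) out[h:1, ] else out[h:1, , ]
    if (bright != 1) out <- pmin(pmax(out * bright, 0), 1)
    out
  }
}

#' Oversampling indices for class-balanced training epochs
#'
#' Minority classes are oversampled (with replacement, from the caller's
#' RNG stream) until every class reaches the majority-class count. Extra
#' copies are flagged so the training loop can pass them through the
#' augmenter; the original images are included exactly once, unflagged.
#'
#' @param labels Integer labels of the training images.
#' @return Data frame with columns `index` (into the training set) and
#'   `augmented` (logical).
#' @export
balanced_epoch_indices <- function(labels) {
  target <- max(table(labels))
  out <- lapply(sort(unique(labels)), function(c) {
    idx <- which(labels == c)
    extra <- target - length(idx)
    rbind(data.frame(index = idx, augmented = FALSE),
          if (extra > 0)
            data.frame(index = sample(idx, extra, replace = TRUE),
                       augmented = TRUE))
  })
  do.call(rbind, out)
}

#' Read a class-per-folder PNG image tree
#'
#' Expects `directory/<class_name>/*.png`; class names are the sorted
#' subdirectory names and become codes `0:(K-1)` via [encode_categories()].
#' RGB images whose channels are identical are collapsed to grayscale
#' matrices.
#'
#' @param directory Root of the tree.
#' @return An [image_bundle] (with a `files` attribute holding the paths).
#' @export
read_image_tree <- function(directory) {
  if (!dir.exists(directory))
    stop(sprintf("no such directory: %s", directory), call. = FALSE)
  classes <- sort(list.dirs(directory, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop("directory contains no class subdirectories", call. = FALSE)
  images <- list(); labels <- integer(0); files <- character(0)
  for (c in seq_along(classes)) {
    fs <- sort(list.files(file.path(directory, classes[c]),
                          pattern = "\\.png$", full.names = TRUE))
    for (f in fs) {
      img <- png::readPNG(f)
      dm <- dim(img)
      if (length(dm) == 3L) {
        if (dm[3] >= 3L &&
            identical(img[, , 1], img[, , 2]) &&
            identical(img[, , 1], img[, , 3])) img <- img[, , 1]
        else if (dm[3] == 1L) img <- img[, , 1]
        else img <- img[, , 1:3]
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, c - 1L)
      files <- c(files, f)
    }
  }
  b <- image_bundle(images, labels, classes)
  attr(b, "files") <- files
  b
}

#' Write a cleaning manifest CSV
#'
#' One row per image: identifier, class name, SNR, and whether the image
#' survived the [clean_dataset()] threshold.
#'
#' @param bundle The original (pre-cleaning) [image_bundle].
#' @param snr Per-image SNR vector (from [clean_dataset()]).
#' @param threshold The SNR threshold used.
#' @param path Output CSV path.
#' @param ids Optional per-image identifiers (defaults to the `files`
#'   attribute or a running index).
#' @return The manifest data frame, invisibly.
#' @export
write_cleaning_manifest <- function(bundle, snr, threshold, path,
                                    ids = NULL) {
  if (is.null(ids)) ids <- attr(bundle, "files")
  if (is.null(ids)) ids <- sprintf("image_%04d", seq_along(bundle$images))
  df <- data.frame(path = ids,
                   class = bundle$class_names[bundle$labels + 1L],
                   snr = snr,
                   kept = snr >= threshold)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
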