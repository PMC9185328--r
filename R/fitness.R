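#' Backbone specification for the fitness harness
#'
#' Names the classifier family used when evaluating a candidate
#' configuration. `toy_cnn` is the in-package CPU-trainable dense softmax
#' network (never pretrained) used by the test suite and the desk-scale
#' loop. The eight pretrained CNN backbones are declared for interface
#' completeness; building them requires an external deep-learning runtime
#' and pretrained weights, so they are plugin points rather than shipped
#' models.
#'
#' @param name One of `"toy_cnn"`, `"DenseNet201"`, `"MobileNet"`,
#'   `"MobileNetV2"`, `"MobileNetV3Small"`, `"MobileNetV3Large"`,
#'   `"VGG16"`, `"VGG19"`, `"Xception"`.
#' @param pretrained_weights `"none"` or `"imagenet"`; `toy_cnn` only
#'   accepts `"none"`.
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(name = "toy_cnn",
                          pretrained_weights = c("none", "imagenet")) {
  allowed <- c("toy_cnn", "DenseNet201", "MobileNet", "MobileNetV2",
               "MobileNetV3Small", "MobileNetV3Large", "VGG16", "VGG19",
               "Xception")
  if (!name %in% allowed)
    stop(sprintf("unknown backbone '%s'", name), call. = FALSE)
  pretrained_weights <- match.arg(pretrained_weights)
  if (name == "toy_cnn" && pretrained_weights != "none")
    stop("toy_cnn never uses pretrained weights", call. = FALSE)
  structure(list(name = name, pretrained_weights = pretrained_weights),
            class = "backbone_spec")
}

#' Training configuration for fitness evaluation
#'
#' @param epochs Training epochs per fitness evaluation; default 5.
#' @param input_size Target image shape for [resize_to_input()]; the
#'   classifier itself trains on `feature_grid^2` block-averaged features.
#' @param feature_grid Side of the average-pooling grid applied to each
#'   (scaled) image before the dense network; default 8 (64 features).
#' @param hidden Hidden-layer widths of the toy network; default
#'   `c(32, 16)`. These are the "backbone" layers that the decoded
#'   fine-tuning ratio freezes or unfreezes.
#' @param lr Learning rate shared by all optimizer rules; default 0.01
#'   (the rate itself is not part of the searched space, so a single
#'   stable value is used for every optimizer).
#' @param eval_on `"all"` evaluates on the entire dataset (the default,
#'   matching the original procedure); `"test"` restricts evaluation to the
#'   held-out test split (leakage-free alternative).
#' @param seed Seed for weight init, batch shuffling, dropout and
#'   augmentation draws; fitness is deterministic given (solution, data,
#'   seed).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 5L, input_size = c(128L, 128L, 3L),
                         feature_grid = 8L, hidden = c(32L, 16L),
                         lr = 0.01, eval_on = c("all", "test"), seed = 1L) {
  stopifnot(epochs >= 1L, feature_grid >= 2L, length(hidden) >= 1L)
  structure(list(epochs = as.integer(epochs), input_size = input_size,
                 feature_grid = as.integer(feature_grid),
                 hidden = as.integer(hidden), lr = lr,
                 eval_on = match.arg(eval_on), seed = as.integer(seed)),
            class = "train_config")
}

# Block-average pooling of an image to a grid x grid feature vector;
# channels are averaged to one intensity plane first.
pool_features <- function(image, grid = 8L) {
  dm <- dim(image)
  gray <- if (length(dm) == 3L) rowMeans(image, dims = 2L) else image
  h <- nrow(gray); w <- ncol(gray)
  ri <- floor((seq_len(h) - 1L) * grid / h) + 1L
  ci <- floor((seq_len(w) - 1L) * grid / w) + 1L
  sums <- rowsum(t(rowsum(gray, ri)), ci)           # grid x grid totals
  cnt <- tabulate(ri, grid) %o% tabulate(ci, grid)
  as.vector(t(sums) / cnt)
}

#' Build a trainable classifier from a decoded configuration
#'
#' Assembles the toy network: `feature_grid^2` inputs, the hidden
#' "backbone" layers, inverted dropout at the configured rate on the last
#' hidden activation, and a `K`-way softmax head, compiled with the decoded
#' loss and optimizer. The decoded fine-tuning ratio unfreezes the trailing
#' `ceiling(ratio/100 * n_backbone)` backbone layers (at least one, counted
#' from the output end); the head is always trainable.
#'
#' Weight initialization draws from the caller's RNG stream.
#'
#' @param backbone A [backbone_spec()]; only `toy_cnn` is buildable.
#' @param config An `hp_config` from [map_solution()].
#' @param K Number of classes (>= 2).
#' @param train_cfg A [train_config()].
#' @return A `classifier` object (layers, trainable flags, loss, optimizer).
#' @export
build_classifier <- function(backbone, config, K,
                             train_cfg = train_config()) {
  stopifnot(inherits(backbone, "backbone_spec"),
            inherits(config, "hp_config"), K >= 2L)
  if (backbone$name != "toy_cnn")
    stop(sprintf(paste0("backbone '%s' requires an external deep-learning",
                        " runtime with pretrained weights; only 'toy_cnn'",
                        " is buildable in-package"), backbone$name),
         call. = FALSE)
  feature_dim <- train_cfg$feature_grid^2
  layers <- new_dense_net(feature_dim, train_cfg$hidden, as.integer(K))
  n_backbone <- length(train_cfg$hidden)
  n_train <- min(max(ceiling(config$tl_learn_ratio / 100 * n_backbone), 1L),
                 n_backbone)
  trainable <- c(rev(seq_len(n_backbone)) <= n_train, TRUE)  # head last
  structure(list(layers = layers, trainable = trainable,
                 loss = config$loss, optimizer = config$optimizer,
                 dropout = config$dropout, batch_size = config$batch_size,
                 K = as.integer(K), feature_dim = feature_dim,
                 lr = train_cfg$lr),
            class = "classifier")
}

#' @export
print.classifier <- function(x, ...) {
  cat(sprintf(paste0("<classifier> toy dense net %d -> %s -> %d softmax |",
                     " loss %s | optimizer %s | dropout %.2f\n"),
              x$feature_dim,
              paste(vapply(x$layers[-length(x$layers)],
                           function(l) ncol(l$W), 0L), collapse = " -> "),
              x$K, x$loss, x$optimizer, x$dropout))
  cat(sprintf("  trainable layers: %s\n",
              paste(which(x$trainable), collapse = ", ")))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param object A trained `classifier`.
#' @param newdata `n x feature_dim` feature matrix.
#' @param ... Unused.
#' @return `n x K` matrix of softmax probabilities (rows sum to 1).
#' @export
predict.classifier <- function(object, newdata, ...) {
  net_forward(object$layers, as.matrix(newdata))$probs
}

#' Train a classifier by mini-batch gradient descent
#'
#' Runs `epochs` passes of shuffled mini-batches of the configured batch
#' size, updating only the trainable layers with the configured optimizer
#' rule. When `balance_fn` is supplied (augmentation on), each epoch's
#' index stream is rebuilt class-balanced and flagged copies are passed
#' through it to obtain fresh augmented feature rows.
#'
#' Consumes the caller's RNG stream (shuffling, dropout, augmentation).
#'
#' @param model A `classifier` from [build_classifier()].
#' @param X `n x feature_dim` training features.
#' @param y Integer labels in `0:(K-1)`.
#' @param epochs Number of epochs.
#' @param balance_fn Optional `function(index) -> feature row` producing an
#'   augmented copy of training image `index`.
#' @return The model with trained weights and a `diverged` flag (non-finite
#'   loss encountered).
#' @export
train_classifier <- function(model, X, y, epochs, balance_fn = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  Y <- matrix(0, n, model$K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  opt <- make_optimizer(model$optimizer, lr = model$lr)
  state <- lapply(model$layers, function(l)
    list(W = opt$init(l$W), b = opt$init(l$b)))
  step <- 0L
  diverged <- FALSE
  for (ep in seq_len(epochs)) {
    if (!is.null(balance_fn)) {
      plan <- balanced_epoch_indices(y)
      plan <- plan[sample.int(nrow(plan)), ]
      Xe <- matrix(NA_real_, nrow(plan), ncol(X))
      Xe[!plan$augmented, ] <- X[plan$index[!plan$augmented], ]
      for (j in which(plan$augmented))
        Xe[j, ] <- balance_fn(plan$index[j])
      Ye <- Y[plan$index, , drop = FALSE]
    } else {
      ord <- sample.int(n)
      Xe <- X[ord, , drop = FALSE]
      Ye <- Y[ord, , drop = FALSE]
    }
    ne <- nrow(Xe)
    starts <- seq(1L, ne, by = model$batch_size)
    for (s in starts) {
      idx <- s:min(s + model$batch_size - 1L, ne)
      acts <- net_forward(model$layers, Xe[idx, , drop = FALSE],
                          dropout_rate = model$dropout, training = TRUE)
      lv <- loss_value(model$loss, Ye[idx, , drop = FALSE], acts$probs)
      if (!is.finite(lv)) { diverged <- TRUE; break }
      dL <- loss_grad_probs(model$loss, Ye[idx, , drop = FALSE], acts$probs)
      grads <- net_backward(model$layers, acts, dL)
      step <- step + 1L
      for (li in seq_along(model$layers)) {
        if (!model$trainable[li]) next
        for (nm in c("W", "b")) {
          res <- opt$step(model$layers[[li]][[nm]], grads[[li]][[nm]],
                          state[[li]][[nm]], step)
          model$layers[[li]][[nm]] <- res$param
          state[[li]][[nm]] <- res$state
        }
      }
    }
    if (diverged) break
  }
  model$diverged <- diverged
  model
}

#' Evaluate the fitness of one solution vector
#'
#' The black-box objective driven by [gto_optimize()]: decodes the solution
#' with [map_solution()], scales every image with the decoded scaling
#' technique, block-averages to feature vectors, trains the classifier on
#' the training split for `train_cfg$epochs` epochs (with class-balanced
#' augmented oversampling when the decoded configuration enables
#' augmentation), and computes the full [metric_report()] on the evaluation
#' set. Fitness is `1 - accuracy` (minimized). The whole evaluation runs on
#' its own RNG stream seeded from `train_cfg$seed`, so identical solutions
#' yield identical fitness and the optimizer's stream is untouched.
#'
#' Training divergence (non-finite loss) yields an `Inf` fitness sentinel.
#'
#' @param solution Numeric vector of length `space$D` in `[0, 1]`.
#' @param bundle An [image_bundle] with split tags (see [split_dataset()]).
#' @param space A `search_space`; default [build_default_space()].
#' @param backbone A [backbone_spec()]; default `toy_cnn`.
#' @param train_cfg A [train_config()].
#' @return A `fitness_result`: list with `fitness`, `config`, `report`
#'   (full metric report, `NULL` on divergence), `confusion`, `loss_value`
#'   (the decoded loss evaluated on the evaluation set) and `diverged`.
#' @export
evaluate_fitness <- function(solution, bundle, space = build_default_space(),
                             backbone = backbone_spec("toy_cnn"),
                             train_cfg = train_config()) {
  stopifnot(inherits(bundle, "image_bundle"))
  if (is.null(bundle$split))
    stop("bundle must be split first (see split_dataset)", call. = FALSE)
  config <- map_solution(solution, space)
  K <- length(bundle$class_names)
  out <- preserve_rng(train_cfg$seed, {
    scaled <- tryCatch(lapply(bundle$images, scale_image,
                              technique = config$scaling_technique),
                       error = function(e) NULL)
    if (is.null(scaled)) {
      list(fitness = Inf, config = config, report = NULL, confusion = NULL,
           loss_value = NA_real_, diverged = TRUE)
    } else {
      feats <- t(vapply(scaled, pool_features, numeric(train_cfg$feature_grid^2),
                        grid = train_cfg$feature_grid))
      tr <- which(bundle$split == "train")
      model <- build_classifier(backbone, config, K, train_cfg)
      balance_fn <- NULL
      if (config$augmentation_active) {
        augmenter <- build_augmenter(config)
        # i indexes the training subset; map back to the bundle image
        balance_fn <- function(i) {
          img <- augmenter(bundle$images[[tr[i]]])
          img <- tryCatch(scale_image(img, config$scaling_technique),
                          error = function(e) img)
          pool_features(img, grid = train_cfg$feature_grid)
        }
      }
      model <- train_classifier(model, feats[tr, , drop = FALSE],
                                bundle$labels[tr], train_cfg$epochs,
                                balance_fn = balance_fn)
      if (isTRUE(model$diverged)) {
        list(fitness = Inf, config = config, report = NULL, confusion = NULL,
             loss_value = NA_real_, diverged = TRUE)
      } else {
        ev <- if (train_cfg$eval_on == "all") seq_along(bundle$images)
              else which(bundle$split == "test")
        probs <- predict(model, feats[ev, , drop = FALSE])
        rep <- metric_report(bundle$labels[ev], probs)
        yv <- matrix(0, length(ev), K)
        yv[cbind(seq_along(ev), bundle$labels[ev] + 1L)] <- 1
        list(fitness = 1 - rep$accuracy, config = config, report = rep,
             confusion = rep$confusion,
             loss_value = loss_value(config$loss, yv, probs),
             diverged = FALSE)
      }
    }
  })
  class(out) <- "fitness_result"
  out
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> fitness %.4f (%s)\n", x$fitness,
              if (x$diverged) "diverged" else
                sprintf("accuracy %.4f", 1 - x$fitness)))
  print(x$config)
  invisible(x)
}

#' Append a fitness result to a run ledger file
#'
#' Writes one JSON line per evaluation: the solution, the decoded
#' configuration, the fitness and headline metrics.
#'
#' @param result A `fitness_result`.
#' @param solution The evaluated solution vector.
#' @param path JSON-lines file to append to.
#' @return `path`, invisibly.
#' @export
append_run_ledger <- function(result, solution, path) {
  cfg <- unclass(result$config)
  rec <- list(solution = as.numeric(solution), config = cfg,
              fitness = result$fitness,
              accuracy = if (is.null(result$report)) NA
                         else result$report$accuracy,
              loss_value = result$loss_value)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
  invisible(path)
}
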