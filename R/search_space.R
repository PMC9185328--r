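#' Hyperparameter specification
#'
#' One entry of a [search space][build_default_space]. A spec describes how a
#' single hyperparameter is decoded from one (or, for `pair-range`, two)
#' elements of a unit-hypercube solution vector.
#'
#' @param name Identifier, e.g. `"batch_size"`.
#' @param kind One of `"categorical"`, `"discrete-numeric"`,
#'   `"continuous-range"`, `"boolean"`, `"pair-range"`.
#' @param domain For list-like kinds (`categorical`, `discrete-numeric`,
#'   `boolean`): the ordered, non-empty vector of allowed values. For
#'   `continuous-range` and `pair-range`: numeric bounds `c(lo, hi)` with
#'   `lo <= hi`.
#' @param slots Number of solution elements consumed: 1, or 2 for
#'   `pair-range`.
#'
#' @return An object of class `hp_spec`.
#' @seealso [map_element()], [map_solution()], [build_default_space()]
#' @export
hp_spec <- function(name, kind, domain, slots = 1L) {
  kind <- match.arg(kind, c("categorical", "discrete-numeric",
                            "continuous-range", "boolean", "pair-range"))
  slots <- as.integer(slots)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            slots %in% c(1L, 2L))
  if (kind == "pair-range" && slots != 2L)
    stop("pair-range specs consume exactly 2 solution slots", call. = FALSE)
  if (kind != "pair-range" && slots != 1L)
    stop("only pair-range specs may consume 2 slots", call. = FALSE)
  if (kind %in% c("continuous-range", "pair-range")) {
    if (length(domain) != 2L || !is.numeric(domain) || domain[1] > domain[2])
      stop("continuous domains must be numeric bounds c(lo, hi) with lo <= hi",
           call. = FALSE)
  } else {
    if (length(domain) < 1L)
      stop("list domains must be non-empty", call. = FALSE)
  }
  structure(list(name = name, kind = kind, domain = domain, slots = slots),
            class = "hp_spec")
}

#' @export
print.hp_spec <- function(x, ...) {
  dom <- if (x$kind %in% c("continuous-range", "pair-range"))
    sprintf("[%g, %g]", x$domain[1], x$domain[2])
  else paste(x$domain, collapse = ", ")
  cat(sprintf("<hp_spec> %s (%s, %d slot%s): %s\n", x$name, x$kind, x$slots,
              if (x$slots > 1) "s" else "", dom))
  invisible(x)
}

#' Default transfer-learning hyperparameter search space
#'
#' Builds the 15-entry ordered search space used throughout the package. The
#' total solution dimensionality is `D = 16`: each hyperparameter consumes a
#' single element of the solution vector except the brightness range, which
#' is an interval and consumes two.
#'
#' The entries, in decoding order, are: loss function (6 choices), batch size
#' (4 to 48 in steps of 4, 12 values), dropout (`[0, 0.6]`), fine-tuning
#' learn ratio (1 to 100 percent of backbone layers unfrozen), weight
#' optimizer (11 choices), image scaling technique (4 choices), the
#' augmentation on/off flag, and the augmentation parameters: rotation
#' (0 to 45 degrees, step 1), width/height shift, shear and zoom
#' (`[0, 0.25]` each), horizontal and vertical flip flags, and the
#' multiplicative brightness interval (`[0.5, 2.0]`, two slots).
#'
#' @return A `search_space` object: list with elements `specs` (ordered list
#'   of [hp_spec] objects) and `D` (total dimensionality, 16).
#' @examples
#' sp <- build_default_space()
#' sp$D                                   # 16
#' map_element(0.75, sp$specs[["batch_size"]])  # 36
#' @export
build_default_space <- function() {
  losses <- c("categorical_crossentropy", "categorical_hinge", "kld",
              "poisson", "squared_hinge", "hinge")
  optimizers <- c("adam", "nadam", "adagrad", "adadelta", "adamax",
                  "rmsprop", "sgd", "ftrl", "sgd_nesterov",
                  "rmsprop_centered", "adam_amsgrad")
  scalers <- c("normalize", "standardize", "minmax", "maxabs")
  specs <- list(
    hp_spec("loss",               "categorical",      losses),
    hp_spec("batch_size",         "discrete-numeric", seq(4L, 48L, by = 4L)),
    hp_spec("dropout",            "continuous-range", c(0, 0.6)),
    hp_spec("tl_learn_ratio",     "discrete-numeric", 1:100),
    hp_spec("optimizer",          "categorical",      optimizers),
    hp_spec("scaling_technique",  "categorical",      scalers),
    hp_spec("apply_augmentation", "boolean",          c(TRUE, FALSE)),
    hp_spec("rotation_deg",       "discrete-numeric", 0:45),
    hp_spec("width_shift",        "continuous-range", c(0, 0.25)),
    hp_spec("height_shift",       "continuous-range", c(0, 0.25)),
    hp_spec("shear",              "continuous-range", c(0, 0.25)),
    hp_spec("zoom",               "continuous-range", c(0, 0.25)),
    hp_spec("horizontal_flip",    "boolean",          c(TRUE, FALSE)),
    hp_spec("vertical_flip",      "boolean",          c(TRUE, FALSE)),
    hp_spec("brightness_range",   "pair-range",       c(0.5, 2.0), slots = 2L)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(specs = specs,
                 D = sum(vapply(specs, `[[`, 0L, "slots"))),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d hyperparameters, D = %d\n",
              length(x$specs), x$D))
  for (s in x$specs) print(s)
  invisible(x)
}

#' Decode one solution element to a concrete hyperparameter value
#'
#' List-like domains of length `L` are decoded with the 1-based index
#' `clamp(ceiling(value * L), 1, L)`; e.g. `0.75` over the 12-value batch-size
#' grid gives index 9, batch size 36. Continuous bounds are decoded by linear
#' interpolation, `lo + value * (hi - lo)`.
#'
#' @param value Numeric scalar in `[0, 1]`.
#' @param spec An [hp_spec]. A `pair-range` spec decodes one element at a
#'   time (each onto its bounds); pairing and ordering happen in
#'   [map_solution()].
#' @return The decoded domain value.
#' @export
map_element <- function(value, spec) {
  stopifnot(inherits(spec, "hp_spec"))
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop("solution elements must be single numbers in [0, 1]", call. = FALSE)
  if (spec$kind %in% c("continuous-range", "pair-range")) {
    lo <- spec$domain[1]; hi <- spec$domain[2]
    return(lo + value * (hi - lo))
  }
  L <- length(spec$domain)
  idx <- min(max(ceiling(value * L), 1L), L)
  spec$domain[[idx]]
}

#' Decode a full solution vector to a hyperparameter configuration
#'
#' Applies [map_element()] spec-by-spec in search-space order; the brightness
#' `pair-range` consumes two consecutive elements, each mapped onto
#' `[0.5, 2.0]`, and the pair is returned sorted ascending. When the
#' augmentation flag decodes to off, all augmentation sub-parameters are
#' still decoded but flagged inactive (`augmentation_active = FALSE`).
#'
#' @param solution Numeric vector of length `space$D`, all elements in
#'   `[0, 1]`.
#' @param space A `search_space`, e.g. [build_default_space()].
#' @return An object of class `hp_config`: named list with fields
#'   `loss`, `batch_size`, `dropout`, `tl_learn_ratio`, `optimizer`,
#'   `scaling_technique`, `apply_augmentation`, `rotation_deg`,
#'   `width_shift`, `height_shift`, `shear`, `zoom`, `horizontal_flip`,
#'   `vertical_flip`, `brightness_range` (length-2 ascending), and
#'   `augmentation_active`.
#' @export
map_solution <- function(solution, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(solution) != space$D)
    stop(sprintf("solution has length %d but the space has D = %d",
                 length(solution), space$D), call. = FALSE)
  out <- list()
  pos <- 1L
  for (s in space$specs) {
    if (s$slots == 2L) {
      pair <- sort(c(map_element(solution[pos], s),
                     map_element(solution[pos + 1L], s)))
      out[[s$name]] <- pair
      pos <- pos + 2L
    } else {
      out[[s$name]] <- map_element(solution[pos], s)
      pos <- pos + 1L
    }
  }
  out$augmentation_active <- isTRUE(out$apply_augmentation)
  structure(out, class = "hp_config")
}

#' @export
print.hp_config <- function(x, ...) {
  cat("<hp_config>\n")
  cat(sprintf("  loss: %s | batch: %d | dropout: %.3f | learn ratio: %d%%\n",
              x$loss, x$batch_size, x$dropout, x$tl_learn_ratio))
  cat(sprintf("  optimizer: %s | scaling: %s\n", x$optimizer,
              x$scaling_technique))
  if (x$augmentation_active) {
    cat(sprintf(paste0("  augmentation: on | rot %d deg | shift (%.2f, %.2f)",
                       " | shear %.2f | zoom %.2f\n"),
                x$rotation_deg, x$width_shift, x$height_shift, x$shear,
                x$zoom))
    cat(sprintf("  flips: h=%s v=%s | brightness [%.2f, %.2f]\n",
                x$horizontal_flip, x$vertical_flip,
                x$brightness_range[1], x$brightness_range[2]))
  } else {
    cat("  augmentation: off (sub-parameters inactive)\n")
  }
  invisible(x)
}

#' Serialize a search space to a YAML config file
#'
#' Writes one key per hyperparameter; list domains as YAML sequences,
#' continuous domains as `[lo, hi]` bounds. [space_from_yaml()] restores the
#' space, including the slot layout.
#'
#' @param space A `search_space`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
space_to_yaml <- function(space, path) {
  stopifnot(inherits(space, "search_space"))
  lst <- lapply(space$specs, function(s)
    list(kind = s$kind, domain = as.vector(s$domain), slots = s$slots))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Restore a search space written by [space_to_yaml()]
#'
#' @param path File path to read.
#' @return A `search_space`.
#' @export
space_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  specs <- lapply(names(lst), function(nm) {
    e <- lst[[nm]]
    dom <- unlist(e$domain)
    if (e$kind %in% c("categorical")) dom <- as.character(dom)
    if (e$kind == "boolean") dom <- as.logical(dom)
    hp_spec(nm, e$kind, dom, slots = e$slots)
  })
  names(specs) <- names(lst)
  structure(list(specs = specs,
                 D = sum(vapply(specs, `[[`, 0L, "slots"))),
            class = "search_space")
}
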