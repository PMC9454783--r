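#' Linear mapping of a unit-interval value onto a bounded range
#'
#' The elementary decoding rule: `lower + v * (upper - lower)`. Every other
#' decoding kind builds on this map. Worked example: a solution value of
#' 0.85 over the dropout range `[0, 0.6]` decodes to `0 + 0.85 * 0.6 = 0.51`.
#'
#' @param v unit-interval value(s)
#' @param lower,upper range bounds, `lower <= upper`
#' @return value(s) in `[lower, upper]`
#' @examples
#' mapContinuous(0.85, 0, 0.6)  # 0.51
#' @export
mapContinuous <- function(v, lower, upper) {
  stopifnot_unit(v, "solution value")
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("invalid bounds: need finite lower <= upper", call. = FALSE)
  lower + v * (upper - lower)
}

#' Linear mapping snapped to a stepped grid
#'
#' Applies [mapContinuous()] then snaps to the nearest point of the grid
#' `lower, lower + step, ..., upper`; ties round toward the larger grid
#' point.
#'
#' @inheritParams mapContinuous
#' @param step positive grid step; `(upper - lower)` must be a multiple
#' @return a grid point in `[lower, upper]`
#' @examples
#' mapStepped(0.45, 4, 48, 4)  # 23.8 snaps to 24
#' @export
mapStepped <- function(v, lower, upper, step) {
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  raw <- mapContinuous(v, lower, upper)
  k <- floor((raw - lower) / step + 0.5 + 1e-12)  # half rounds up
  pmin(upper, lower + k * step)
}

#' Equal-width categorical decoding
#'
#' Partitions the unit interval into `K = length(categories)` equal cells;
#' `v` selects `categories[floor(v * K) + 1]`, with `v = 1` clamped into
#' the last cell so the map is total on `[0, 1]`.
#'
#' @inheritParams mapContinuous
#' @param categories ordered, non-empty label vector
#' @return a single label
#' @export
mapCategorical <- function(v, categories) {
  stopifnot_unit(v, "solution value")
  if (length(categories) < 1L) stop("empty category list", call. = FALSE)
  k <- length(categories)
  categories[pmin(floor(v * k), k - 1) + 1]
}

#' Boolean decoding with an upper-inclusive 0.5 threshold
#'
#' @inheritParams mapContinuous
#' @return `FALSE` when `v < 0.5`, `TRUE` otherwise
#' @export
mapBoolean <- function(v) {
  stopifnot_unit(v, "solution value")
  v >= 0.5
}

hpSpec <- function(index, name, kind, lower = NA_real_, upper = NA_real_,
                   step = NA_real_, categories = character(0),
                   conditional = FALSE) {
  new("HyperparameterSpec", index = as.integer(index), name = name,
      kind = kind, lower = lower, upper = upper, step = step,
      categories = categories, conditional = conditional)
}

#' Loss, optimizer and scaler label sets of the default search space
#'
#' @return character vector of labels, in encoding order
#' @export
lossLabels <- function() c("Categorical Crossentropy", "Categorical Hinge",
                           "KLDivergence", "Poisson", "Squared Hinge", "Hinge")

#' @rdname lossLabels
#' @export
optimizerLabels <- function() c("Adam", "NAdam", "AdaGrad", "AdaDelta",
                                "AdaMax", "RMSProp", "SGD", "Ftrl",
                                "SGD Nesterov", "RMSProp Centered",
                                "Adam AMSGrad")

#' @rdname lossLabels
#' @export
scalerLabels <- function() c("Normalize", "Standard", "MinMax", "MaxAbs")

#' The default 15-element hyperparameter search space
#'
#' Element order and ranges: (1) training loss over six candidates,
#' (2) batch size 4..48 step 4, (3) dropout `[0, 0.6]`, (4) transfer-learning
#' learn ratio 1..100 percent, (5) optimizer over eleven candidates,
#' (6) per-image scaler over four candidates, (7) augmentation on/off, and —
#' active only when (7) decodes to yes — (8) rotation 0..45 degrees,
#' (9)-(12) width shift / height shift / shear / zoom `[0, 0.25]`,
#' (13)-(14) horizontal/vertical flips, (15) brightness multiplier range
#' centred inside `[0.5, 2.0]`.
#'
#' @return a [HyperparameterSpace-class]
#' @export
defaultSearchSpace <- function() {
  new("HyperparameterSpace", specs = list(
    hpSpec(1, "loss", "categorical", categories = lossLabels()),
    hpSpec(2, "batch_size", "stepped", 4, 48, 4),
    hpSpec(3, "dropout", "continuous", 0, 0.6),
    hpSpec(4, "tl_learn_ratio", "stepped", 1, 100, 1),
    hpSpec(5, "optimizer", "categorical", categories = optimizerLabels()),
    hpSpec(6, "scaler", "categorical", categories = scalerLabels()),
    hpSpec(7, "augment", "boolean"),
    hpSpec(8, "rotation", "stepped", 0, 45, 1, conditional = TRUE),
    hpSpec(9, "width_shift", "continuous", 0, 0.25, conditional = TRUE),
    hpSpec(10, "height_shift", "continuous", 0, 0.25, conditional = TRUE),
    hpSpec(11, "shear", "continuous", 0, 0.25, conditional = TRUE),
    hpSpec(12, "zoom", "continuous", 0, 0.25, conditional = TRUE),
    hpSpec(13, "horizontal_flip", "boolean", conditional = TRUE),
    hpSpec(14, "vertical_flip", "boolean", conditional = TRUE),
    hpSpec(15, "brightness", "interval", 0.5, 2.0, conditional = TRUE)
  ))
}

decodeElement <- function(spec, v) {
  switch(spec@kind,
    continuous = mapContinuous(v, spec@lower, spec@upper),
    stepped = mapStepped(v, spec@lower, spec@upper, spec@step),
    categorical = mapCategorical(v, spec@categories),
    boolean = mapBoolean(v),
    interval = mapContinuous(v, spec@lower, spec@upper),
    stop(sprintf("unknown spec kind '%s'", spec@kind), call. = FALSE)
  )
}

#' Decode an encoded solution vector into a training configuration
#'
#' Each of the 15 unit-interval elements is decoded by its element spec.
#' When element 7 (augmentation switch) decodes to `FALSE` the trailing
#' eight policy elements are marked inactive (`NA`): the vector always
#' carries 15 elements so the optimizer works in fixed dimension, but only
#' 7 are active. The brightness element decodes to a centre `c` and is
#' emitted as the interval `[c (1 - w), c (1 + w)]` clipped to the element
#' bounds, with half-width fraction `w = brightnessHalfWidth`.
#'
#' @param x numeric vector of 15 values in `[0, 1]`
#' @param space a [HyperparameterSpace-class]
#' @param brightnessHalfWidth half-width fraction of the emitted
#'   brightness interval (default 0.05)
#' @return a [DecodedConfig-class]
#' @examples
#' x <- rep(0.5, 15); x[3] <- 0.85
#' decodeSolution(x, defaultSearchSpace())
#' @export
decodeSolution <- function(x, space = defaultSearchSpace(),
                           brightnessHalfWidth = 0.05) {
  if (!is(space, "HyperparameterSpace")) stop("malformed search space", call. = FALSE)
  validObject(space)
  if (length(x) != 15L) stop("solution vector must have 15 elements", call. = FALSE)
  stopifnot_unit(x, "solution vector")
  sp <- space@specs
  augment <- decodeElement(sp[[7]], x[7])
  dec <- function(i) decodeElement(sp[[i]], x[i])
  if (augment) {
    bspec <- sp[[15]]
    centre <- dec(15)
    br <- c(centre * (1 - brightnessHalfWidth), centre * (1 + brightnessHalfWidth))
    br <- pmin(bspec@upper, pmax(bspec@lower, br))
    new("DecodedConfig",
        loss = dec(1), batchSize = dec(2), dropout = dec(3),
        tlLearnRatio = dec(4), optimizer = dec(5), scaler = dec(6),
        augment = TRUE, rotation = dec(8), widthShift = dec(9),
        heightShift = dec(10), shear = dec(11), zoom = dec(12),
        horizontalFlip = dec(13), verticalFlip = dec(14), brightness = br)
  } else {
    new("DecodedConfig",
        loss = dec(1), batchSize = dec(2), dropout = dec(3),
        tlLearnRatio = dec(4), optimizer = dec(5), scaler = dec(6),
        augment = FALSE, rotation = NA_real_, widthShift = NA_real_,
        heightShift = NA_real_, shear = NA_real_, zoom = NA_real_,
        horizontalFlip = NA, verticalFlip = NA,
        brightness = c(NA_real_, NA_real_))
  }
}

#' Active encoding dimension of a decoded configuration
#'
#' The encoded vector always has 15 slots, but only the first 7 influence
#' training when augmentation is off.
#'
#' @param config a [DecodedConfig-class]
#' @return 15 when augmentation is active, 7 otherwise
#' @export
activeDimension <- function(config) {
  stopifnot(is(config, "DecodedConfig"))
  if (config@augment) 15L else 7L
}

specToList <- function(s) {
  out <- list(index = s@index, name = s@name, kind = s@kind)
  if (!is.na(s@lower)) out$lower <- s@lower
  if (!is.na(s@upper)) out$upper <- s@upper
  if (!is.na(s@step)) out$step <- s@step
  if (length(s@categories)) out$categories <- as.list(s@categories)
  out$conditional <- s@conditional
  out
}

#' Read / write a search space as a YAML file
#'
#' The YAML mirrors the element table (index, name, kind, bounds, step,
#' categories, conditional flag) so ranges can be narrowed or category
#' lists swapped without code changes.
#'
#' @param space a [HyperparameterSpace-class]
#' @param path file path
#' @return `readSearchSpace` returns a [HyperparameterSpace-class];
#'   `writeSearchSpace` returns `path` invisibly
#' @export
writeSearchSpace <- function(space, path) {
  validObject(space)
  yaml::write_yaml(list(elements = lapply(space@specs, specToList)), path)
  invisible(path)
}

#' @rdname writeSearchSpace
#' @export
readSearchSpace <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$elements, function(e) {
    hpSpec(e$index, e$name, e$kind,
           lower = e$lower %||% NA_real_, upper = e$upper %||% NA_real_,
           step = e$step %||% NA_real_,
           categories = as.character(unlist(e$categories %||% character(0))),
           conditional = isTRUE(e$conditional))
  })
  sp <- new("HyperparameterSpace", specs = specs)
  validObject(sp)
  sp
}

#' @describeIn HyperparameterSpace-class compact element table
#' @param object a `HyperparameterSpace`
#' @export
setMethod("show", "HyperparameterSpace", function(object) {
  cat("HyperparameterSpace with", length(object@specs), "elements\n")
  for (s in object@specs) {
    rng <- switch(s@kind,
      categorical = paste0("{", paste(s@categories, collapse = ", "), "}"),
      boolean = "{no, yes}",
      stepped = sprintf("[%g..%g step %g]", s@lower, s@upper, s@step),
      sprintf("[%g, %g]", s@lower, s@upper))
    cat(sprintf("  %2d %-16s %-11s %s%s\n", s@index, s@name, s@kind, rng,
                if (s@conditional) "  (conditional)" else ""))
  }
})

#' @describeIn DecodedConfig-class print the decoded settings
#' @param object a `DecodedConfig`
#' @export
setMethod("show", "DecodedConfig", function(object) {
  cat("DecodedConfig\n")
  cat(sprintf("  loss: %s | optimizer: %s | scaler: %s\n",
              object@loss, object@optimizer, object@scaler))
  cat(sprintf("  batch size: %d | dropout: %.3f | TL learn ratio: %d%%\n",
              as.integer(object@batchSize), object@dropout,
              as.integer(object@tlLearnRatio)))
  if (object@augment) {
    cat(sprintf("  augmentation: rotation %g deg, shifts (%.3f, %.3f), shear %.3f, zoom %.3f\n",
                object@rotation, object@widthShift, object@heightShift,
                object@shear, object@zoom))
    cat(sprintf("  flips: h=%s v=%s | brightness [%.3f, %.3f]\n",
                object@horizontalFlip, object@verticalFlip,
                object@brightness[1], object@brightness[2]))
  } else cat("  augmentation: off (active dimension 7)\n")
})
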