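#' @import methods
NULL

#' Search-space description for one encoded hyperparameter
#'
#' Each element of a solution vector decodes through one spec. `kind`
#' selects the decoding rule: `"continuous"` (linear map onto
#' `[lower, upper]`), `"stepped"` (linear map snapped to the grid
#' `lower, lower+step, ...`), `"categorical"` (equal-width partition of
#' the unit interval over `categories`), `"boolean"` (threshold at 0.5,
#' upper-inclusive) and `"interval"` (linear map to a centre, emitted as
#' a symmetric multiplier interval, used for the brightness element).
#'
#' @slot index integer position of the element (1..15)
#' @slot name human-readable hyperparameter label
#' @slot kind one of `"continuous"`, `"stepped"`, `"categorical"`,
#'   `"boolean"`, `"interval"`
#' @slot lower,upper numeric bounds (NA for categorical/boolean)
#' @slot step grid step (stepped kind only, NA otherwise)
#' @slot categories ordered label vector (categorical kind only)
#' @slot conditional logical; `TRUE` for the augmentation-policy elements
#'   (indices 8-15) that are only active when augmentation is switched on
#' @export
setClass("HyperparameterSpec",
  representation(
    index = "integer", name = "character", kind = "character",
    lower = "numeric", upper = "numeric", step = "numeric",
    categories = "character", conditional = "logical"
  ),
  prototype(lower = NA_real_, upper = NA_real_, step = NA_real_,
            categories = character(0), conditional = FALSE)
)

setValidity("HyperparameterSpec", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("continuous", "stepped", "categorical", "boolean", "interval"))
    msgs <- c(msgs, sprintf("unknown kind '%s'", object@kind))
  if (object@kind %in% c("continuous", "stepped", "interval")) {
    if (is.na(object@lower) || is.na(object@upper))
      msgs <- c(msgs, "numeric kinds need lower and upper bounds")
    else if (object@lower > object@upper)
      msgs <- c(msgs, "lower must not exceed upper")
  }
  if (object@kind == "stepped") {
    if (is.na(object@step) || object@step <= 0)
      msgs <- c(msgs, "stepped kind needs step > 0")
    else {
      k <- (object@upper - object@lower) / object@step
      if (abs(k - round(k)) > 1e-8)
        msgs <- c(msgs, "(upper - lower) must be a multiple of step")
    }
  }
  if (object@kind == "categorical" && length(object@categories) == 0)
    msgs <- c(msgs, "categorical kind needs a non-empty category list")
  if (length(msgs)) msgs else TRUE
})

#' Ordered search space of 15 encoded hyperparameters
#'
#' Container for the full encoded search space: exactly 15
#' [HyperparameterSpec-class] entries in fixed order. Use
#' [defaultSearchSpace()] for the published configuration and
#' [readSearchSpace()]/[writeSearchSpace()] for the YAML round trip.
#'
#' @slot specs list of 15 `HyperparameterSpec` objects, indices 1..15
#' @export
setClass("HyperparameterSpace", representation(specs = "list"))

setValidity("HyperparameterSpace", function(object) {
  msgs <- character(0)
  if (length(object@specs) != 15L)
    msgs <- c(msgs, "a search space has exactly 15 element specs")
  else {
    ok <- vapply(object@specs, is, logical(1), class2 = "HyperparameterSpec")
    if (!all(ok)) msgs <- c(msgs, "specs must be HyperparameterSpec objects")
    else {
      idx <- vapply(object@specs, slot, integer(1), name = "index")
      if (!identical(idx, 1:15))
        msgs <- c(msgs, "spec indices must be 1..15 in order")
      cond <- vapply(object@specs, slot, logical(1), name = "conditional")
      if (!identical(cond, c(rep(FALSE, 7), rep(TRUE, 8))))
        msgs <- c(msgs, "exactly elements 8-15 must be conditional")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Decoded training configuration
#'
#' The concrete hyperparameter settings obtained by decoding a unit-interval
#' solution vector against a [HyperparameterSpace-class]. When `augment` is
#' `FALSE` the augmentation-policy slots are `NA` (inactive) and the active
#' encoding dimension is 7; otherwise it is 15.
#'
#' @slot loss training loss label
#' @slot batchSize images per optimization step
#' @slot dropout dropout fraction applied before the classification head
#' @slot tlLearnRatio percentage of backbone layers left trainable
#' @slot optimizer weight-optimizer label
#' @slot scaler per-image dimensional-scaling label
#' @slot augment logical; apply the decoded augmentation policy in training
#' @slot rotation rotation half-range in degrees (NA when inactive)
#' @slot widthShift,heightShift,shear,zoom augmentation fractions
#' @slot horizontalFlip,verticalFlip flip switches
#' @slot brightness length-2 multiplier interval (NA when inactive)
#' @export
setClass("DecodedConfig",
  representation(
    loss = "character", batchSize = "numeric", dropout = "numeric",
    tlLearnRatio = "numeric", optimizer = "character", scaler = "character",
    augment = "logical", rotation = "numeric", widthShift = "numeric",
    heightShift = "numeric", shear = "numeric", zoom = "numeric",
    horizontalFlip = "logical", verticalFlip = "logical",
    brightness = "numeric"
  )
)

setValidity("DecodedConfig", function(object) {
  msgs <- character(0)
  if (object@dropout < 0 || object@dropout > 1)
    msgs <- c(msgs, "dropout must be a fraction")
  if (object@batchSize < 1) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@augment) {
    if (length(object@brightness) != 2L || any(is.na(object@brightness)))
      msgs <- c(msgs, "active brightness must be a length-2 interval")
  }
  if (length(msgs)) msgs else TRUE
})

#' MRFO population state
#'
#' The swarm state carried through the optimization loop: the current
#' solution matrix (one row per manta ray, columns are unit-interval
#' encoded coordinates), the matching fitness scores, and the greedily
#' retained incumbent best.
#'
#' @slot solutions numeric matrix, `nMax` x `dimension`, entries kept inside
#'   the search bounds by clipping (the unit hypercube for the encoded space)
#' @slot scores numeric vector of fitness values (NA before first scoring)
#' @slot bestSolution numeric vector, the incumbent best encoded point
#' @slot bestScore numeric scalar, never decreases across updates
#' @slot iteration integer, current iteration counter
#' @export
setClass("MantaPopulation",
  representation(
    solutions = "matrix", scores = "numeric",
    bestSolution = "numeric", bestScore = "numeric", iteration = "integer"
  )
)

setValidity("MantaPopulation", function(object) {
  msgs <- character(0)
  if (nrow(object@solutions) < 1L) msgs <- c(msgs, "population must be non-empty")
  if (length(object@scores) != nrow(object@solutions))
    msgs <- c(msgs, "one score per solution required")
  if (any(!is.finite(object@solutions)))
    msgs <- c(msgs, "solutions must be finite (bound clipping is the updates' job)")
  if (length(msgs)) msgs else TRUE
})

#' Result of an MRFO run
#'
#' @slot bestSolution best encoded point found
#' @slot bestScore its fitness
#' @slot history data.frame with one row per fitness evaluation
#'   (columns: iteration, member, sweep, score, bestScore)
#' @slot params the run parameters (as returned by [mrfoParams()])
#' @export
setClass("MRFORun",
  representation(bestSolution = "numeric", bestScore = "numeric",
                 history = "data.frame", params = "list")
)

#' Aggregated confusion-matrix counts
#'
#' True/false positive/negative totals from which the whole metric suite
#' derives. For multiclass problems the counts are micro-aggregated:
#' per-class one-vs-rest 2x2 tables summed over classes.
#'
#' @slot tp,tn,fp,fn non-negative counts
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) return("counts must be non-negative")
  if (sum(v) <= 0) return("at least one count must be positive")
  TRUE
})
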