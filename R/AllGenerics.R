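#' @rdname accessors
#' @param x an object with an incumbent best solution
#' @export
setGeneric("bestSolution", function(x) standardGeneric("bestSolution"))

#' @rdname accessors
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname accessors
#' @export
setGeneric("solutions", function(x) standardGeneric("solutions"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("history", function(x) standardGeneric("history"))

#' Equalize per-class sample counts by augmentation-based up-sampling
#'
#' Minority classes are up-sampled until every class matches the largest
#' class. The numeric method does the count arithmetic only; the list
#' method up-samples an in-memory image dataset by drawing existing class
#' members with replacement and passing them through a randomized
#' augmentation policy ([buildAugmenter()]). Originals are never removed.
#'
#' @param x named per-class counts, or an image dataset list with
#'   elements `images` (list of H x W x 3 arrays) and `labels`
#' @param ... method-specific arguments (`policy`, `seed`)
#' @return same shape as `x` with equalized class counts
#' @export
setGeneric("balanceClasses", function(x, ...) standardGeneric("balanceClasses"))

#' @rdname computeMetrics
#' @export
setGeneric("computeMetrics", function(x, ...) standardGeneric("computeMetrics"))

#' Accessors for optimization and metric containers
#'
#' `bestSolution`/`bestScore` return the incumbent optimum,
#' `solutions`/`scores` the current population, and `history` the
#' per-evaluation trace of a finished run.
#'
#' @name accessors
NULL
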