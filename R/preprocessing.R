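# Keys bicubic convolution kernel, a = -0.5
cubicKernel <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# sparse-ish row-weight matrix for 1-D bicubic resampling from n to m
# samples; pixel centres at (k + 0.5)/n, source indices clamped at edges
bicubicWeights <- function(n, m) {
  W <- matrix(0, m, n)
  scale <- n / m
  for (j in seq_len(m)) {
    src <- (j - 0.5) * scale + 0.5        # 1-based source coordinate
    base <- floor(src - 2) + 1
    idx <- base:(base + 3)
    w <- cubicKernel(src - idx)
    w <- w / sum(w)
    idx <- pmin(n, pmax(1, idx))          # clamp border taps
    for (k in seq_along(idx)) W[j, idx[k]] <- W[j, idx[k]] + w[k]
  }
  W
}

#' Resize an image to the network input size with bicubic interpolation
#'
#' Resamples to `size x size x 3` using separable bicubic convolution
#' (Keys kernel, a = -0.5) with clamped borders. Single-channel inputs are
#' replicated to three channels before resampling; an input already at the
#' target size is returned unchanged.
#'
#' @param img numeric array `H x W` or `H x W x C`, `C` in \{1, 3\},
#'   intensities on the raw 0..255 scale
#' @param size output side length (default 128)
#' @return numeric array `size x size x 3`
#' @export
resizeImage <- function(img, size = 128L) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (length(d) != 3L || !(d[3] %in% c(1L, 3L)) || d[1] < 1 || d[2] < 1)
    stop("expected an H x W x {1,3} image array", call. = FALSE)
  if (d[3] == 1L) img <- array(rep(img, 3L), c(d[1], d[2], 3L))
  if (d[1] == size && d[2] == size) return(img)
  Wr <- bicubicWeights(dim(img)[1], size)
  Wc <- bicubicWeights(dim(img)[2], size)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
  out
}

#' Per-image dimensional scaling
#'
#' Applies one of the four scaling transforms, with statistics computed on
#' the single image: `Normalize` divides by the image maximum, `Standard`
#' centres by the image mean and divides by its standard deviation,
#' `MinMax` maps the image range onto `[0, 1]`, and `MaxAbs` divides by the
#' largest absolute intensity.
#'
#' @param img numeric image array
#' @param method one of `"Normalize"`, `"Standard"`, `"MinMax"`, `"MaxAbs"`
#' @param degenerate what to do when the transform is undefined (constant
#'   image for `Standard`/`MinMax`, all-zero image for the ratio scalers):
#'   `"error"` signals a condition, `"zero"` substitutes a zero image
#' @return scaled image array of the same shape
#' @export
applyScaler <- function(img, method = scalerLabels(),
                        degenerate = c("error", "zero")) {
  method <- match.arg(method)
  degenerate <- match.arg(degenerate)
  fail <- function(msg) {
    if (degenerate == "zero") return(array(0, dim(img)))
    stop(msg, call. = FALSE)
  }
  switch(method,
    Normalize = {
      m <- max(img)
      if (m == 0) fail("degenerate image: max is 0") else img / m
    },
    Standard = {
      s <- stats::sd(img)
      if (s == 0) fail("degenerate image: zero variance") else (img - mean(img)) / s
    },
    MinMax = {
      lo <- min(img); hi <- max(img)
      if (hi == lo) fail("degenerate image: constant intensities")
      else (img - lo) / (hi - lo)
    },
    MaxAbs = {
      m <- max(abs(img))
      if (m == 0) fail("degenerate image: all zero") else img / m
    }
  )
}

#' Augmentation policy
#'
#' A randomized geometric/photometric policy: rotation (uniform in the
#' +/- half-range), width/height shifts (fractions of the image side),
#' shear, zoom, a brightness multiplier drawn uniformly from an interval,
#' and optional flips. [defaultAugmentationPolicy()] returns the balancing
#' policy used before optimization: rotation 30 degrees, 20% shifts, shear
#' and zoom, brightness `[0.8, 1.2]`, both flips enabled.
#'
#' @param rotation rotation half-range, degrees
#' @param widthShift,heightShift shift half-ranges, fraction of the side
#' @param shear shear half-range (shear factor)
#' @param zoom zoom half-range; scale drawn in `[1 - zoom, 1 + zoom]`
#' @param brightness length-2 multiplier interval
#' @param horizontalFlip,verticalFlip enable the flips (each applied with
#'   probability `flipProb` by the augmenter)
#' @return a policy list
#' @export
augmentationPolicy <- function(rotation = 0, widthShift = 0, heightShift = 0,
                               shear = 0, zoom = 0, brightness = c(1, 1),
                               horizontalFlip = FALSE, verticalFlip = FALSE) {
  stopifnot(length(brightness) == 2L, brightness[1] <= brightness[2],
            rotation >= 0, widthShift >= 0, heightShift >= 0,
            shear >= 0, zoom >= 0)
  list(rotation = rotation, widthShift = widthShift, heightShift = heightShift,
       shear = shear, zoom = zoom, brightness = brightness,
       horizontalFlip = horizontalFlip, verticalFlip = verticalFlip)
}

#' @rdname augmentationPolicy
#' @export
defaultAugmentationPolicy <- function() {
  augmentationPolicy(rotation = 30, widthShift = 0.2, heightShift = 0.2,
                     shear = 0.2, zoom = 0.2, brightness = c(0.8, 1.2),
                     horizontalFlip = TRUE, verticalFlip = TRUE)
}

configToPolicy <- function(config) {
  stopifnot(is(config, "DecodedConfig"))
  if (!config@augment) return(augmentationPolicy())
  augmentationPolicy(rotation = config@rotation,
                     widthShift = config@widthShift,
                     heightShift = config@heightShift,
                     shear = config@shear, zoom = config@zoom,
                     brightness = config@brightness,
                     horizontalFlip = config@horizontalFlip,
                     verticalFlip = config@verticalFlip)
}

#' Build a randomized image augmenter from a policy
#'
#' Returns a `function(img)` applying one random draw of the policy each
#' call: a combined centre-anchored rotation/shear/zoom/shift warp
#' (bilinear, zero fill), flips with probability `flipProb` each, and a
#' brightness multiplier clipped back to `[0, 255]`. When every geometric
#' parameter is zero, flips are disabled and brightness is `[1, 1]`, the
#' returned transform is the exact identity.
#'
#' @param policy an [augmentationPolicy()] list or a [DecodedConfig-class]
#' @param flipProb probability of applying each enabled flip (default 0.5;
#'   set to 1 to force flips)
#' @return `function(img)` mapping an `H x W x 3` array to a transformed
#'   array of the same shape
#' @export
buildAugmenter <- function(policy, flipProb = 0.5) {
  if (is(policy, "DecodedConfig")) policy <- configToPolicy(policy)
  geom <- policy$rotation > 0 || policy$widthShift > 0 ||
    policy$heightShift > 0 || policy$shear > 0 || policy$zoom > 0
  function(img) {
    d <- dim(img)
    if (geom) {
      theta <- stats::runif(1, -policy$rotation, policy$rotation) * pi / 180
      sh <- stats::runif(1, -policy$shear, policy$shear)
      sc <- stats::runif(1, 1 - policy$zoom, 1 + policy$zoom)
      dy <- stats::runif(1, -policy$heightShift, policy$heightShift) * d[1]
      dx <- stats::runif(1, -policy$widthShift, policy$widthShift) * d[2]
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      Sh <- matrix(c(1, 0, sh, 1), 2)
      M <- (R %*% Sh) * sc
      centre <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
      offset <- centre - as.vector(centre %*% M) + c(dy, dx)
      m <- rbind(M, offset)
      img <- unclass(EBImage::affine(img, m, filter = "bilinear", bg.col = 0))
      img <- array(as.numeric(img), d)
    }
    if (policy$horizontalFlip && stats::runif(1) < flipProb)
      img <- img[, d[2]:1, , drop = FALSE]
    if (policy$verticalFlip && stats::runif(1) < flipProb)
      img <- img[d[1]:1, , , drop = FALSE]
    b <- policy$brightness
    if (b[1] != 1 || b[2] != 1) {
      img <- img * stats::runif(1, b[1], b[2])
      img <- pmin(255, pmax(img, 0))
    }
    array(img, d)
  }
}

#' @describeIn balanceClasses count arithmetic only: every class is raised
#'   to the maximum input count
setMethod("balanceClasses", "numeric", function(x, ...) {
  if (length(x) < 1L || any(x < 1)) stop("need at least one class with count >= 1", call. = FALSE)
  out <- rep(max(x), length(x))
  names(out) <- names(x)
  out
})

#' @describeIn balanceClasses up-sample an in-memory dataset
#'   (`list(images=, labels=)`) by augmenting resampled minority-class
#'   members with `policy` (default: the balancing policy)
#' @param policy augmentation policy used to synthesize new images
#' @param seed integer seed for the resampling and augmentation draws
setMethod("balanceClasses", "list", function(x, policy = defaultAugmentationPolicy(),
                                             seed = NULL, ...) {
  stopifnot(!is.null(x$images), !is.null(x$labels),
            length(x$images) == length(x$labels))
  if (!is.null(seed)) set.seed(seed)
  augment <- buildAugmenter(policy)
  key <- as.character(x$labels)
  counts <- table(key)
  target <- max(counts)
  images <- x$images
  labels <- x$labels
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0) next
    pool <- which(key == cl)
    picks <- sample(pool, deficit, replace = TRUE)
    for (p in picks) {
      images[[length(images) + 1]] <- augment(x$images[[p]])
      labels <- c(labels, x$labels[p])
    }
  }
  out <- x
  out$images <- images
  out$labels <- labels
  out
})

apportion <- function(total, weights) {
  # largest-remainder apportionment of `total` over classes
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified two-stage train/validation/test split
#'
#' First splits the full index set into training and test subsets at the
#' given ratio (test share `1 - ratio`, size rounded half-up), then splits
#' the training subset again at the same ratio into training and
#' validation. Both stages are stratified by class (per-class sizes by
#' largest-remainder apportionment) and shuffled under the seed. Classes
#' too small to stratify trigger a warning and an unstratified fallback.
#'
#' @param n number of items
#' @param labels per-item class labels (length `n`); `NULL` for
#'   unstratified splitting
#' @param ratio training share at each stage (default 0.85)
#' @param seed integer seed for the shuffles
#' @return list with integer index vectors `train`, `validation`, `test`
#'   (disjoint, covering `1..n`) and the `ratio`
#' @export
splitDataset <- function(n, labels = NULL, ratio = 0.85, seed = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0,1)", call. = FALSE)
  if (n < 3) stop("need at least 3 items to split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have length n", call. = FALSE)

  stratified <- !is.null(labels)
  if (stratified && min(table(labels)) < 3) {
    warning("a class has fewer members than the split granularity; falling back to unstratified splitting",
            call. = FALSE)
    stratified <- FALSE
  }

  holdOut <- function(ids, labs, k) {
    # draw k held-out ids, stratified over labs when available
    if (is.null(labs)) return(sample(ids, k))
    counts <- table(labs)
    kPer <- apportion(k, as.numeric(counts))
    names(kPer) <- names(counts)
    unlist(lapply(names(counts), function(cl) {
      sample(ids[labs == cl], kPer[[cl]])
    }), use.names = FALSE)
  }

  labs <- if (stratified) as.character(labels) else NULL
  all <- seq_len(n)
  nTest <- halfUpInt((1 - ratio) * n)
  test <- holdOut(all, labs, nTest)
  trainPool <- setdiff(all, test)
  nVal <- halfUpInt((1 - ratio) * length(trainPool))
  validation <- holdOut(trainPool, if (is.null(labs)) NULL else labs[trainPool], nVal)
  train <- setdiff(trainPool, validation)
  list(train = sort(train), validation = sort(validation),
       test = sort(test), ratio = ratio)
}

#' Write a split assignment as a CSV manifest
#'
#' One row per item with its identifier (file path or index), class label
#' and split assignment (`train`, `validation` or `test`).
#'
#' @param split a [splitDataset()] result
#' @param labels per-item class labels
#' @param path output CSV path
#' @param items optional per-item identifiers (e.g. file paths); defaults
#'   to the indices `1..n`
#' @return `path`, invisibly
#' @export
writeSplitManifest <- function(split, labels, path, items = NULL) {
  n <- length(labels)
  assign <- rep(NA_character_, n)
  assign[split$train] <- "train"
  assign[split$validation] <- "validation"
  assign[split$test] <- "test"
  df <- data.frame(item = if (is.null(items)) seq_len(n) else items,
                   class = labels, split = assign)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
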