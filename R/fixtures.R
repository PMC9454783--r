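#' Specification of a synthetic textured image dataset
#'
#' Desk-scale stand-in for a class-per-subdirectory image corpus: each
#' class renders a deterministic base pattern — a sinusoidal stripe texture
#' with class-specific orientation and frequency on a class-specific base
#' intensity — plus i.i.d. Gaussian pixel noise. Class-dependent base
#' intensity makes the dataset learnable by a simple mean-intensity
#' threshold, which end-to-end smoke tests use as their chance-beating
#' oracle; the stripe texture keeps the images non-trivial.
#'
#' @param nClasses number of classes, >= 2
#' @param nPerClass images per class before imbalance multipliers
#' @param imageSize side length in pixels (default 128)
#' @param noiseSd Gaussian noise standard deviation, raw intensity units
#' @param imbalance optional per-class multipliers on `nPerClass`
#' @param seed integer seed; generation is fully reproducible
#' @return a spec list for [generateImageDataset()]
#' @export
syntheticDatasetSpec <- function(nClasses = 2, nPerClass = 50, imageSize = 128,
                                 noiseSd = 10, imbalance = NULL, seed = 1) {
  stopifnot(nClasses >= 2, nPerClass >= 1, imageSize >= 8, noiseSd >= 0)
  if (!is.null(imbalance)) stopifnot(length(imbalance) == nClasses, all(imbalance > 0))
  list(nClasses = as.integer(nClasses), nPerClass = as.integer(nPerClass),
       imageSize = as.integer(imageSize), noiseSd = noiseSd,
       imbalance = imbalance, seed = as.integer(seed))
}

classPattern <- function(k, nClasses, size) {
  # deterministic per-class texture: oriented stripes on a class offset
  theta <- pi * (k - 1) / nClasses
  freq <- 2 + 2 * k
  offset <- 60 + 120 * (k - 1) / max(1, nClasses - 1)
  xy <- seq_len(size) / size
  phase <- outer(cos(theta) * xy, sin(theta) * xy, "+")
  base <- offset + 40 * sin(2 * pi * freq * phase)
  pmin(255, pmax(0, base))
}

#' Generate a labeled synthetic image dataset
#'
#' @param spec a [syntheticDatasetSpec()]
#' @return list with `images` (list of `size x size x 3` arrays, 0..255),
#'   `labels` (integer, 1-based), `classes` (character names) and `spec`
#' @export
generateImageDataset <- function(spec) {
  set.seed(spec$seed)
  counts <- rep(spec$nPerClass, spec$nClasses)
  if (!is.null(spec$imbalance)) counts <- as.integer(round(counts * spec$imbalance))
  classes <- sprintf("class%02d", seq_len(spec$nClasses))
  images <- vector("list", sum(counts))
  labels <- integer(sum(counts))
  pos <- 0L
  for (k in seq_len(spec$nClasses)) {
    base <- classPattern(k, spec$nClasses, spec$imageSize)
    for (j in seq_len(counts[k])) {
      pos <- pos + 1L
      noisy <- base + matrix(stats::rnorm(spec$imageSize^2, 0, spec$noiseSd),
                             spec$imageSize)
      noisy <- pmin(255, pmax(0, noisy))
      images[[pos]] <- array(rep(noisy, 3L), c(spec$imageSize, spec$imageSize, 3L))
      labels[pos] <- k
    }
  }
  list(images = images, labels = labels, classes = classes, spec = spec)
}

#' Write a dataset to a class-per-subdirectory PNG folder
#'
#' Mirrors the layout of the real image corpora (one subdirectory per
#' class), so anything that reads image folders can also read materialized
#' synthetic data.
#'
#' @param dataset a dataset list (`images`, `labels`, `classes`)
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
materializeDataset <- function(dataset, dir) {
  for (k in seq_along(dataset$classes))
    dir.create(file.path(dir, dataset$classes[k]), recursive = TRUE, showWarnings = FALSE)
  counters <- integer(length(dataset$classes))
  for (i in seq_along(dataset$images)) {
    k <- dataset$labels[i]
    counters[k] <- counters[k] + 1L
    path <- file.path(dir, dataset$classes[k], sprintf("img%04d.png", counters[k]))
    png::writePNG(dataset$images[[i]] / 255, path)
  }
  invisible(dir)
}

#' Read a class-per-subdirectory image folder
#'
#' Each immediate subdirectory is a class; PNG and JPEG files are read and
#' returned on the raw 0..255 intensity scale as `H x W x 3` arrays
#' (grayscale replicated to three channels).
#'
#' @param dir dataset directory
#' @return dataset list (`images`, `labels`, `classes`)
#' @export
loadImageFolder <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("dataset directory not found: %s", dir), call. = FALSE)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop(sprintf("no class subdirectories in %s", dir), call. = FALSE)
  images <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(dir, classes[k]),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f) * 255
      } else {
        x <- EBImage::readImage(f) * 255
        if (length(dim(x)) == 3L) aperm(as.array(x), c(2, 1, 3)) else t(as.array(x))
      }
      if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
      if (dim(img)[3] > 3L) img <- img[, , 1:3]  # drop alpha
      if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k)
    }
  }
  if (length(images) == 0) stop(sprintf("no images found under %s", dir), call. = FALSE)
  list(images = images, labels = labels, classes = classes)
}

#' Published confusion-count fixtures
#'
#' The per-model TP/TN/FP/FN totals printed for the two breast-imaging
#' studies: the binary histopathology experiment (8 models) and the
#' three-class ultrasound experiment (8 models). These serve as
#' verification fixtures for the metric suite.
#'
#' @return list with named [ConfusionCounts-class] collections `binary`
#'   and `threeclass`
#' @export
publishedConfusionFixtures <- function() {
  binary <- list(
    InceptionV3    = confusionCounts(10288, 10288, 320, 320),
    Xception       = confusionCounts(10363, 10363, 241, 241),
    EfficientNetB7 = confusionCounts(7916, 7916, 2668, 2668),
    NASNetLarge    = confusionCounts(9817, 9817, 791, 791),
    VGG19          = confusionCounts(10308, 10308, 300, 300),
    SeNet154       = confusionCounts(10171, 10171, 413, 413),
    DenseNet201    = confusionCounts(10350, 10350, 242, 242),
    ResNet152V2    = confusionCounts(10225, 10225, 383, 383)
  )
  threeclass <- list(
    InceptionV3    = confusionCounts(1191, 2521, 55, 97),
    Xception       = confusionCounts(1267, 2584, 32, 41),
    EfficientNetB7 = confusionCounts(875, 2475, 117, 421),
    NASNetLarge    = confusionCounts(1184, 2575, 41, 124),
    VGG19          = confusionCounts(1053, 2471, 121, 243),
    SeNet154       = confusionCounts(1257, 2572, 36, 47),
    DenseNet201    = confusionCounts(1204, 2491, 61, 72),
    ResNet152V2    = confusionCounts(1294, 2603, 13, 14)
  )
  list(binary = binary, threeclass = threeclass)
}

#' Published per-class image counts before balancing
#'
#' The class compositions of the two studied corpora: the binary
#' histopathology dataset (Benign 2479, Malignant 5304; 7783 images) and
#' the three-class ultrasound dataset (Benign 437, Malignant 210, Normal
#' 133; 780 images). Balancing up-samples each to the majority count,
#' giving totals 10608 and 1311.
#'
#' @return list of named per-class count vectors `binary` and `ultrasound`
#' @export
imbalanceFixture <- function() {
  list(binary = c(Benign = 2479, Malignant = 5304),
       ultrasound = c(Benign = 437, Malignant = 210, Normal = 133))
}
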