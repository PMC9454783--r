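# shared builders for the suite: a small learnable dataset, its splits, and
# an independent threshold-classifier oracle

makeTinyDataset <- function(nPerClass = 40, size = 32, noiseSd = 10, seed = 7,
                            nClasses = 2, imbalance = NULL) {
  generateImageDataset(syntheticDatasetSpec(
    nClasses = nClasses, nPerClass = nPerClass, imageSize = size,
    noiseSd = noiseSd, imbalance = imbalance, seed = seed))
}

makeSplits <- function(ds, seed = 11, ratio = 0.85) {
  sp <- splitDataset(length(ds$images), ds$labels, ratio = ratio, seed = seed)
  sub <- function(ids) list(images = ds$images[ids], labels = ds$labels[ids])
  list(train = sub(sp$train), validation = sub(sp$validation),
       test = sub(sp$test), classes = ds$classes)
}

# independent oracle: a one-feature threshold classifier on the mean
# intensity of the upper-left quadrant, fit on one half, tested on the other
quadrantThresholdAccuracy <- function(ds, seed = 3) {
  stopifnot(length(ds$classes) == 2)
  feat <- vapply(ds$images, function(im) {
    q <- dim(im)[1] %/% 2
    mean(im[1:q, 1:q, 1])
  }, numeric(1))
  set.seed(seed)
  n <- length(feat)
  fitIds <- sample(n, n %/% 2)
  m1 <- mean(feat[fitIds][ds$labels[fitIds] == 1])
  m2 <- mean(feat[fitIds][ds$labels[fitIds] == 2])
  thr <- (m1 + m2) / 2
  testIds <- setdiff(seq_len(n), fitIds)
  pred <- ifelse((feat[testIds] > thr) == (m2 > m1), 2, 1)
  mean(pred == ds$labels[testIds])
}

# enumeration oracle for micro-aggregated confusion counts
microCountsOracle <- function(yTrue, yPred, nClasses) {
  tot <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (k in seq_len(nClasses) - 1) {
    t1 <- yTrue == k; p1 <- yPred == k
    tot <- tot + c(sum(t1 & p1), sum(!t1 & !p1), sum(!t1 & p1), sum(t1 & !p1))
  }
  tot
}
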