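test_that("bicubic resize honours shape, constants, and identity", {
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  out <- resizeImage(img, 128)
  expect_equal(dim(out), c(128L, 128L, 3L))
  # constant image stays constant under interpolation
  flat <- array(37, c(50, 70, 3))
  expect_equal(unique(as.vector(resizeImage(flat, 128))), 37)
  # already at target size: untouched
  at <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_identical(resizeImage(at, 128), at)
  # grayscale replicated to three channels
  g <- matrix(runif(40 * 40, 0, 255), 40)
  rg <- resizeImage(g, 16)
  expect_equal(dim(rg), c(16L, 16L, 3L))
  expect_equal(rg[, , 1], rg[, , 3])
  expect_error(resizeImage(array(0, c(4, 4, 2))), "image array")
})

test_that("bicubic resize interpolates a smooth ramp more closely than nearest sampling", {
  ramp <- array(rep(seq(0, 255, length.out = 64), 64), c(64, 64, 1))
  out <- resizeImage(ramp, 128)
  truth <- seq(0, 255, length.out = 128)
  # interior of a linear ramp is reproduced nearly exactly by cubic kernels
  expect_lt(max(abs(out[5:124, 1, 1] - truth[5:124])), 1.5)
})

test_that("the four scalers satisfy their defining contracts", {
  set.seed(2)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_equal(max(applyScaler(img, "Normalize")), 1)
  st <- applyScaler(img, "Standard")
  expect_lt(abs(mean(st)), 1e-6)
  expect_lt(abs(sd(st) - 1), 1e-6)
  mm <- applyScaler(img, "MinMax")
  expect_equal(range(mm), c(0, 1))
  expect_equal(applyScaler(array(c(0, 128, 255), c(1, 3, 1)), "MinMax"),
               array(c(0, 128 / 255, 1), c(1, 3, 1)))
  ma <- applyScaler(img, "MaxAbs")
  expect_equal(max(abs(ma)), 1)
  # re-applying MinMax to a MinMax output is the identity
  expect_equal(applyScaler(mm, "MinMax"), mm)
})

test_that("degenerate images signal or substitute according to policy", {
  flat <- array(5, c(4, 4, 3))
  expect_error(applyScaler(flat, "Standard"), "degenerate")
  expect_error(applyScaler(flat, "MinMax"), "degenerate")
  expect_equal(unique(as.vector(applyScaler(flat, "Standard", degenerate = "zero"))), 0)
  zero <- array(0, c(4, 4, 3))
  expect_error(applyScaler(zero, "Normalize"), "degenerate")
})

test_that("class balancing reproduces the published dataset totals", {
  counts <- imbalanceFixture()
  b <- balanceClasses(counts$binary)
  expect_equal(unname(b), c(5304, 5304))
  expect_equal(sum(b), 10608)
  u <- balanceClasses(counts$ultrasound)
  expect_equal(unname(u), c(437, 437, 437))
  expect_equal(sum(u), 1311)
  # already balanced: unchanged
  expect_equal(unname(balanceClasses(c(a = 7, b = 7))), c(7, 7))
  expect_error(balanceClasses(numeric(0)))
})

test_that("dataset balancing conserves the original images and equalizes classes", {
  ds <- makeTinyDataset(nPerClass = 12, size = 16, imbalance = c(1, 0.5))
  bal <- balanceClasses(ds, seed = 3)
  expect_equal(as.integer(table(bal$labels)), c(12L, 12L))
  # originals are a prefix of the balanced set
  expect_identical(bal$images[seq_along(ds$images)], ds$images)
  expect_identical(bal$labels[seq_along(ds$labels)], ds$labels)
  expect_true(is.integer(bal$labels))
})

test_that("the double split has the documented sizes and is a disjoint cover", {
  s <- splitDataset(1000, labels = rep(1:2, 500), ratio = 0.85, seed = 12)
  expect_length(s$test, 150)
  expect_length(s$validation, 128)
  expect_length(s$train, 722)
  expect_setequal(c(s$train, s$validation, s$test), 1:1000)
  expect_length(intersect(s$train, s$test), 0)
  expect_length(intersect(s$validation, s$test), 0)
  s2 <- splitDataset(1000, labels = rep(1:2, 500), ratio = 0.85, seed = 12)
  expect_identical(s, s2)
  # stratification: class shares preserved in every subset
  labs <- rep(1:2, 500)
  expect_equal(sum(labs[s$test] == 1), 75)
  expect_equal(sum(labs[s$validation] == 1), 64)
})

test_that("the split manifest records every item's class and assignment", {
  labs <- rep(c("a", "b"), 30)
  s <- splitDataset(60, labs, seed = 4)
  path <- tempfile(fileext = ".csv")
  writeSplitManifest(s, labs, path, items = sprintf("img%02d.png", 1:60))
  df <- read.csv(path)
  expect_equal(nrow(df), 60)
  expect_false(anyNA(df$split))
  expect_equal(sum(df$split == "test"), length(s$test))
  expect_identical(df$class[s$test], labs[s$test])
})

test_that("split fractions converge to 15% test / 72.25% train", {
  for (n in c(400, 2000, 8000)) {
    s <- splitDataset(n, ratio = 0.85, seed = 1)
    expect_lt(abs(length(s$test) / n - 0.15), 0.01)
    expect_lt(abs(length(s$train) / n - 0.7225), 0.01)
  }
  expect_warning(splitDataset(10, labels = c(rep(1, 8), 2, 2), seed = 1),
                 "unstratified")
  expect_error(splitDataset(100, ratio = 1.2), "ratio")
})

test_that("the augmenter is the identity for a null policy and flips are involutions", {
  img <- array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3))
  ident <- buildAugmenter(augmentationPolicy())
  expect_identical(ident(img), img)
  hflip <- buildAugmenter(augmentationPolicy(horizontalFlip = TRUE), flipProb = 1)
  expect_equal(hflip(hflip(img)), img)
  expect_false(identical(hflip(img), img))
  vflip <- buildAugmenter(augmentationPolicy(verticalFlip = TRUE), flipProb = 1)
  expect_equal(vflip(vflip(img)), img)
})

test_that("rotating a centred disk preserves its pixel mass within tolerance", {
  n <- 64
  xy <- expand.grid(r = 1:n, c = 1:n)
  disk <- matrix(as.numeric((xy$r - 32.5)^2 + (xy$c - 32.5)^2 < 14^2) * 200, n)
  img <- array(rep(disk, 3), c(n, n, 3))
  rot <- buildAugmenter(augmentationPolicy(rotation = 30))
  set.seed(8)
  for (k in 1:5) {
    out <- rot(img)
    expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.01)
  }
})

test_that("the default balancing policy matches the published settings", {
  p <- defaultAugmentationPolicy()
  expect_equal(p$rotation, 30)
  expect_equal(p$shear, 0.2)
  expect_equal(p$zoom, 0.2)
  expect_equal(p$widthShift, 0.2)
  expect_equal(p$heightShift, 0.2)
  expect_equal(p$brightness, c(0.8, 1.2))
  expect_true(p$horizontalFlip && p$verticalFlip)
})

test_that("a decoded configuration drives the augmenter", {
  x <- rep(0.5, 15); x[7] <- 0.9; x[13] <- 0.9; x[14] <- 0.1
  cfg <- decodeSolution(x)
  aug <- buildAugmenter(cfg)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  set.seed(1)
  out <- aug(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
})
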