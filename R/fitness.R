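.backboneRegistry <- new.env(parent = emptyenv())

#' Backbone provider registry
#'
#' A backbone provider is a `function(inputSize, seed)` returning a feature
#' extractor: a list with `name`, `layers` (ordered layer list) and
#' `featureDim`. The package ships the `"tiny"` provider — a fixed
#' average-pooling stem followed by two seeded dense tanh layers — which is
#' small enough to train on a CPU in seconds. The eight published
#' large-scale backbone names are pre-registered as stubs that fail fast:
#' supplying them requires registering a provider backed by an external
#' deep-learning runtime.
#'
#' @param name backbone name
#' @param provider `function(inputSize, seed)` returning a backbone
#' @return `registerBackbone` the name invisibly; `getBackbone` the
#'   provider; `listBackbones` all registered names
#' @export
registerBackbone <- function(name, provider) {
  stopifnot(is.character(name), is.function(provider))
  assign(name, provider, envir = .backboneRegistry)
  invisible(name)
}

#' @rdname registerBackbone
#' @export
getBackbone <- function(name) {
  if (!exists(name, envir = .backboneRegistry))
    stop(sprintf("backbone '%s' is not registered; see registerBackbone()", name),
         call. = FALSE)
  get(name, envir = .backboneRegistry)
}

#' @rdname registerBackbone
#' @export
listBackbones <- function() sort(ls(.backboneRegistry))

# block average-pool an H x W x 3 image to out x out x 3, flattened
poolFeatures <- function(img, out) {
  d <- dim(img)
  gr <- floor((seq_len(d[1]) - 1) * out / d[1]) + 1
  gc <- floor((seq_len(d[2]) - 1) * out / d[2]) + 1
  cnt <- tabulate(gr, out) %o% tabulate(gc, out)
  feats <- vapply(1:3, function(ch) {
    s <- rowsum(img[, , ch], gr)
    s <- t(rowsum(t(s), gc))
    as.vector(s / cnt)
  }, numeric(out * out))
  as.vector(feats)
}

glorot <- function(fanIn, fanOut) {
  l <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -l, l), fanIn, fanOut)
}

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @rdname registerBackbone
#' @param inputSize expected image side length
#' @param seed seed for the deterministic layer initialization (the
#'   provider's stand-in for pre-trained weights)
#' @export
tinyBackboneProvider <- function(inputSize = 32, seed = 42) {
  withLocalSeed(seed, {
    d0 <- 8 * 8 * 3
    list(name = "tiny", inputSize = inputSize, featureDim = 16L,
         layers = list(
           list(type = "pool", out = 8L),
           list(type = "dense", W = glorot(d0, 32), b = rep(0, 32)),
           list(type = "dense", W = glorot(32, 16), b = rep(0, 16))
         ))
  })
}

unavailableProvider <- function(name) {
  force(name)
  function(inputSize = 128, seed = 42)
    stop(sprintf(paste("backbone '%s' requires an external deep-learning",
                       "provider; register one with registerBackbone()"), name),
         call. = FALSE)
}

publishedBackboneNames <- function()
  c("InceptionV3", "Xception", "EfficientNetB7", "NASNetLarge",
    "VGG19", "SeNet154", "DenseNet201", "ResNet152V2")

registerDefaultBackbones <- function() {
  registerBackbone("tiny", tinyBackboneProvider)
  for (nm in publishedBackboneNames())
    registerBackbone(nm, unavailableProvider(nm))
}

#' Partition backbone layers into frozen and trainable sets
#'
#' The trailing `ceiling(learnRatio/100 * L)` layers are left trainable and
#' the leading layers frozen — the interpretation of the learn/freeze ratio
#' where fine-tuning touches the layers closest to the classification head.
#' Set `direction = "leading"` to flip the interpretation.
#'
#' @param layers ordered layer list (or a backbone list with `$layers`),
#'   or a single integer layer count
#' @param learnRatio percentage in 0..100
#' @param direction which end of the network stays trainable
#' @return list with integer index vectors `trainable` and `frozen`
#' @export
freezeLayers <- function(layers, learnRatio, direction = c("trailing", "leading")) {
  direction <- match.arg(direction)
  if (is.list(layers) && !is.null(layers$layers)) layers <- layers$layers
  L <- if (is.numeric(layers)) as.integer(layers) else length(layers)
  if (L < 1) stop("invalid backbone: empty layer list", call. = FALSE)
  if (learnRatio < 0 || learnRatio > 100)
    stop("learnRatio must be in 0..100", call. = FALSE)
  k <- min(L, ceiling(learnRatio / 100 * L))
  trainable <- if (k == 0) integer(0)
  else if (direction == "trailing") (L - k + 1):L else 1:k
  list(trainable = trainable, frozen = setdiff(seq_len(L), trainable))
}

# ---- losses -----------------------------------------------------------------
# Each loss returns the gradient of the mean per-sample loss with respect to
# the softmax logits; P are softmax outputs, Y one-hot targets (n x K).

softmaxChain <- function(P, dLdP) {
  # dL/dz = P * (dL/dP - rowSums(P * dL/dP))
  P * (dLdP - rowSums(P * dLdP))
}

lossGradient <- function(label, P, Y) {
  n <- nrow(P); K <- ncol(P)
  eps <- 1e-9
  switch(label,
    "Categorical Crossentropy" = (P - Y) / n,
    "KLDivergence" = (P - Y) / n,  # one-hot targets: same logit gradient as CE
    "Poisson" = {
      dLdP <- (1 - Y / pmax(P, eps)) / (n * K)
      softmaxChain(P, dLdP)
    },
    "Hinge" = {
      Ypm <- 2 * Y - 1
      act <- (1 - Ypm * P) > 0
      dLdP <- (-Ypm * act) / (n * K)
      softmaxChain(P, dLdP)
    },
    "Squared Hinge" = {
      Ypm <- 2 * Y - 1
      m <- pmax(0, 1 - Ypm * P)
      dLdP <- (-2 * Ypm * m) / (n * K)
      softmaxChain(P, dLdP)
    },
    "Categorical Hinge" = {
      pos <- rowSums(Y * P)
      negP <- P; negP[Y == 1] <- -Inf
      negIdx <- max.col(negP, ties.method = "first")
      act <- (1 - pos + negP[cbind(seq_len(n), negIdx)]) > 0
      dLdP <- -Y
      dLdP[cbind(seq_len(n), negIdx)] <- dLdP[cbind(seq_len(n), negIdx)] + 1
      dLdP <- dLdP * act / n
      softmaxChain(P, dLdP)
    },
    stop(sprintf("unknown loss label '%s'", label), call. = FALSE)
  )
}

# ---- optimizers -------------------------------------------------------------
# makeOptimizer returns step(param, grad, state) -> list(param, state),
# covering the eleven optimizer labels of the search space.

makeOptimizer <- function(label, lr = 0.05) {
  eps <- 1e-7
  b1 <- 0.9; b2 <- 0.999; mom <- 0.9; rho <- 0.95
  newState <- function(p) list(m = p * 0, v = p * 0, vhat = p * 0,
                               g2 = p * 0, dx2 = p * 0, z = p * 0,
                               nacc = p * 0, t = 0)
  stepFun <- switch(label,
    "SGD" = function(p, g, s) list(param = p - lr * g, state = s),
    "SGD Nesterov" = function(p, g, s) {
      s$m <- mom * s$m - lr * g
      list(param = p + mom * s$m - lr * g, state = s)
    },
    "Adam" = function(p, g, s) {
      s$t <- s$t + 1
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mh <- s$m / (1 - b1^s$t); vh <- s$v / (1 - b2^s$t)
      list(param = p - lr * mh / (sqrt(vh) + eps), state = s)
    },
    "Adam AMSGrad" = function(p, g, s) {
      s$t <- s$t + 1
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      s$vhat <- pmax(s$vhat, s$v)
      mh <- s$m / (1 - b1^s$t)
      list(param = p - lr * mh / (sqrt(s$vhat) + eps), state = s)
    },
    "NAdam" = function(p, g, s) {
      s$t <- s$t + 1
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mh <- (b1 * s$m + (1 - b1) * g) / (1 - b1^(s$t + 1))
      vh <- s$v / (1 - b2^s$t)
      list(param = p - lr * mh / (sqrt(vh) + eps), state = s)
    },
    "AdaMax" = function(p, g, s) {
      s$t <- s$t + 1
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- pmax(b2 * s$v, abs(g))
      list(param = p - lr / (1 - b1^s$t) * s$m / (s$v + eps), state = s)
    },
    "AdaGrad" = function(p, g, s) {
      s$g2 <- s$g2 + g^2
      list(param = p - lr * g / (sqrt(s$g2) + eps), state = s)
    },
    "AdaDelta" = function(p, g, s) {
      s$g2 <- rho * s$g2 + (1 - rho) * g^2
      dx <- -sqrt(s$dx2 + eps) / sqrt(s$g2 + eps) * g
      s$dx2 <- rho * s$dx2 + (1 - rho) * dx^2
      list(param = p + lr * dx, state = s)
    },
    "RMSProp" = function(p, g, s) {
      s$v <- rho * s$v + (1 - rho) * g^2
      list(param = p - lr * g / (sqrt(s$v) + eps), state = s)
    },
    "RMSProp Centered" = function(p, g, s) {
      s$v <- rho * s$v + (1 - rho) * g^2
      s$m <- rho * s$m + (1 - rho) * g
      list(param = p - lr * g / (sqrt(s$v - s$m^2 + eps)), state = s)
    },
    "Ftrl" = function(p, g, s) {
      # FTRL-proximal without regularization reduces to per-coordinate
      # adaptive gradient descent
      gn <- s$g2 + g^2
      sigma <- (sqrt(gn) - sqrt(s$g2)) / lr
      s$z <- s$z + g - sigma * p
      s$g2 <- gn
      list(param = -lr * s$z / (sqrt(s$g2) + eps), state = s)
    },
    stop(sprintf("unknown optimizer label '%s'", label), call. = FALSE)
  )
  list(step = stepFun, init = newState)
}

# ---- network training -------------------------------------------------------

denseLayerIdx <- function(backbone)
  which(vapply(backbone$layers, function(l) l$type == "dense", logical(1)))

forwardDense <- function(backbone, X) {
  acts <- list(X)
  for (l in backbone$layers) {
    if (l$type != "dense") next
    X <- tanh(sweep(X %*% l$W, 2, l$b, "+"))
    acts[[length(acts) + 1]] <- X
  }
  acts
}

# featurize a list of images through the pooling stem
stemFeatures <- function(backbone, images) {
  out <- backbone$layers[[1]]$out
  t(vapply(images, poolFeatures, numeric(out * out * 3), out = out))
}

#' Training-run settings
#'
#' The per-evaluation training settings that are not part of the encoded
#' search space. Defaults: 5 epochs, softmax output head, step size 0.05
#' (sized for the shipped `"tiny"` backbone).
#'
#' @param epochs training epochs, >= 1
#' @param learningRate optimizer step size
#' @param evalSplit split scored as fitness: `"validation"` (default) keeps
#'   selection honest; `"whole"` reproduces evaluating on the entire
#'   dataset, which leaks training data into selection and is provided only
#'   as an explicit opt-in; `"test"` is for the final report, not selection
#' @return settings list
#' @export
trainingRun <- function(epochs = 5, learningRate = 0.05,
                        evalSplit = c("validation", "whole", "test")) {
  stopifnot(epochs >= 1, learningRate > 0)
  list(epochs = as.integer(epochs), learningRate = learningRate,
       evalSplit = match.arg(evalSplit))
}

scaleImages <- function(images, method)
  lapply(images, applyScaler, method = method, degenerate = "zero")

#' Train a configured classifier and score it (the transfer-learning fitness)
#'
#' Builds the model — backbone feature extractor, dropout at the configured
#' rate, and a softmax head sized to the class count — then trains it for
#' `run$epochs` epochs with the configured loss, optimizer and batch size.
#' The configured per-image scaler is applied to every image; when the
#' configuration switches augmentation on, its decoded policy is applied to
#' each training batch. Backbone layers are partitioned by
#' [freezeLayers()] according to the configured learn ratio; frozen layers
#' keep their initial ("pre-trained") weights. The returned fitness score
#' is classification accuracy on `run$evalSplit`.
#'
#' A training collapse (non-finite activations or weights) scores 0 with a
#' diagnostic warning rather than aborting the surrounding optimization.
#'
#' @param config a [DecodedConfig-class]
#' @param data list of splits `train`, `validation`, `test`, each a
#'   `list(images, labels)` with 1-based integer labels, plus `classes`
#' @param backbone a backbone object (from a registered provider)
#' @param run a [trainingRun()] settings list
#' @param seed seed for the training-time randomness (shuffling, dropout,
#'   augmentation); evaluation restores the caller's random stream
#' @param returnPredictions return the per-item predictions alongside the
#'   score (used for the final metric report)
#' @return accuracy in `[0, 1]` on the evaluation split, or — with
#'   `returnPredictions = TRUE` — a list with `score`, `predicted`, `actual`
#' @export
evaluateTransferFitness <- function(config, data, backbone,
                                    run = trainingRun(), seed = 1,
                                    returnPredictions = FALSE) {
  stopifnot(is(config, "DecodedConfig"))
  if (!config@loss %in% lossLabels())
    stop(sprintf("unknown loss label '%s'", config@loss), call. = FALSE)
  if (!config@optimizer %in% optimizerLabels())
    stop(sprintf("unknown optimizer label '%s'", config@optimizer), call. = FALSE)
  withLocalSeed(seed, {
    nClasses <- length(data$classes)
    dIdx <- denseLayerIdx(backbone)
    part <- freezeLayers(backbone$layers, config@tlLearnRatio)
    trainableDense <- intersect(dIdx, part$trainable)

    trainImgs <- data$train$images
    trainY <- data$train$labels
    Yhot <- diag(nClasses)[trainY, , drop = FALSE]
    augmenter <- if (config@augment) buildAugmenter(config) else NULL
    # pooled features are reusable across epochs when no augmentation runs
    baseFeat <- if (is.null(augmenter))
      stemFeatures(backbone, scaleImages(trainImgs, config@scaler)) else NULL

    opt <- makeOptimizer(config@optimizer, lr = run$learningRate)
    featDim <- backbone$featureDim
    headW <- withLocalSeed(seed + 1, glorot(featDim, nClasses))
    headB <- rep(0, nClasses)
    states <- list(headW = opt$init(headW), headB = opt$init(headB))
    for (j in trainableDense) {
      states[[paste0("W", j)]] <- opt$init(backbone$layers[[j]]$W)
      states[[paste0("b", j)]] <- opt$init(backbone$layers[[j]]$b)
    }

    p <- config@dropout
    n <- length(trainImgs)
    batch <- max(1L, min(as.integer(config@batchSize), n))
    collapsed <- FALSE

    for (epoch in seq_len(run$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        ids <- ord[start:min(start + batch - 1, n)]
        X <- if (is.null(augmenter)) baseFeat[ids, , drop = FALSE]
        else stemFeatures(backbone,
               scaleImages(lapply(trainImgs[ids], augmenter), config@scaler))
        acts <- forwardDense(backbone, X)
        Z <- acts[[length(acts)]]
        mask <- if (p > 0)
          matrix(stats::rbinom(length(Z), 1, 1 - p), nrow(Z)) / (1 - p)
        else 1
        Zd <- Z * mask
        logits <- sweep(Zd %*% headW, 2, headB, "+")
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits); P <- P / rowSums(P)
        if (any(!is.finite(P))) { collapsed <- TRUE; break }
        G <- lossGradient(config@loss, P, Yhot[ids, , drop = FALSE])
        gW <- crossprod(Zd, G); gB <- colSums(G)
        delta <- (G %*% t(headW)) * mask
        upd <- opt$step(headW, gW, states$headW); headW <- upd$param; states$headW <- upd$state
        upd <- opt$step(headB, gB, states$headB); headB <- upd$param; states$headB <- upd$state
        # backprop through the dense stack (reverse order)
        for (pos in rev(seq_along(dIdx))) {
          j <- dIdx[pos]
          H <- acts[[pos + 1]]; Hin <- acts[[pos]]
          dPre <- delta * (1 - H^2)
          if (j %in% trainableDense) {
            gWj <- crossprod(Hin, dPre); gBj <- colSums(dPre)
            kW <- paste0("W", j); kB <- paste0("b", j)
            upd <- opt$step(backbone$layers[[j]]$W, gWj, states[[kW]])
            backbone$layers[[j]]$W <- upd$param; states[[kW]] <- upd$state
            upd <- opt$step(backbone$layers[[j]]$b, gBj, states[[kB]])
            backbone$layers[[j]]$b <- upd$param; states[[kB]] <- upd$state
          }
          if (pos > 1) delta <- dPre %*% t(backbone$layers[[j]]$W)
        }
        if (any(!is.finite(headW)) ||
            any(vapply(dIdx, function(j) any(!is.finite(backbone$layers[[j]]$W)),
                       logical(1)))) { collapsed <- TRUE; break }
      }
      if (collapsed) break
    }
    if (collapsed) {
      warning(sprintf("training collapsed (non-finite values) under loss '%s'/optimizer '%s'; scoring 0",
                      config@loss, config@optimizer), call. = FALSE)
      return(if (returnPredictions)
        list(score = 0, predicted = integer(0), actual = integer(0)) else 0)
    }

    evalSet <- switch(run$evalSplit,
      validation = data$validation,
      test = data$test,
      whole = list(images = c(data$train$images, data$validation$images,
                              data$test$images),
                   labels = c(data$train$labels, data$validation$labels,
                              data$test$labels)))
    Xe <- stemFeatures(backbone, scaleImages(evalSet$images, config@scaler))
    Ze <- forwardDense(backbone, Xe)
    Ze <- Ze[[length(Ze)]]
    logits <- sweep(Ze %*% headW, 2, headB, "+")
    pred <- max.col(logits, ties.method = "first")
    acc <- mean(pred == evalSet$labels)
    if (returnPredictions)
      list(score = acc, predicted = pred, actual = evalSet$labels)
    else acc
  })
}

#' Wrap the transfer fitness for the optimizer
#'
#' Returns a `function(x)` over encoded solution vectors: decode against
#' `space`, then train-and-score via [evaluateTransferFitness()].
#' Evaluations are memoized on the decoded configuration, so the roughly
#' three score sweeps per iteration do not retrain identical
#' configurations; training is seeded per call so a configuration always
#' scores the same. Optionally appends one JSON line per fresh evaluation
#' (decoded config, score, duration, seed) to `logFile`.
#'
#' @param data split dataset (see [evaluateTransferFitness()])
#' @param backbone backbone object
#' @param run a [trainingRun()] list
#' @param space a [HyperparameterSpace-class]
#' @param seed training seed handed to every evaluation
#' @param logFile optional JSON-lines log path
#' @return fitness closure for [runMRFO()]
#' @export
makeTransferFitness <- function(data, backbone, run = trainingRun(),
                                space = defaultSearchSpace(), seed = 1,
                                logFile = NULL) {
  cache <- new.env(parent = emptyenv())
  function(x) {
    config <- decodeSolution(x, space)
    key <- configKey(config)
    if (!is.null(cache[[key]])) return(cache[[key]])
    t0 <- proc.time()[["elapsed"]]
    score <- evaluateTransferFitness(config, data, backbone, run, seed)
    cache[[key]] <- score
    if (!is.null(logFile)) {
      rec <- c(configAsList(config),
               list(score = score, seconds = proc.time()[["elapsed"]] - t0,
                    seed = seed))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = logFile, append = TRUE)
    }
    score
  }
}

configAsList <- function(config) {
  list(loss = config@loss, batchSize = config@batchSize,
       dropout = config@dropout, tlLearnRatio = config@tlLearnRatio,
       optimizer = config@optimizer, scaler = config@scaler,
       augment = config@augment, rotation = config@rotation,
       widthShift = config@widthShift, heightShift = config@heightShift,
       shear = config@shear, zoom = config@zoom,
       horizontalFlip = config@horizontalFlip,
       verticalFlip = config@verticalFlip,
       brightness = config@brightness)
}

configKey <- function(config) {
  paste(vapply(configAsList(config), function(v)
    paste(format(v, digits = 10), collapse = ","), character(1)),
    collapse = "|")
}

#' Analytic test objective
#'
#' A smooth unimodal stand-in for the expensive training objective:
#' `1 / (1 + sum((x - centre)^2))`, maximal (exactly 1) at `centre` and
#' strictly decreasing with distance from it. Useful for verifying
#' optimizer behaviour against a known optimum.
#'
#' @param x position vector
#' @param centre target point (default: hypercube centre)
#' @return score in `(0, 1]`
#' @examples
#' analyticFitness(c(0.5, 0.5))           # 1
#' analyticFitness(0, centre = 0.5)       # 0.8
#' @export
analyticFitness <- function(x, centre = rep(0.5, length(x))) {
  1 / (1 + sum((x - centre)^2))
}
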