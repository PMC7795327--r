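# Compact convolutional network for time-frequency images.
#
# One or two input branches (spectrogram and/or mel spectrogram), each a
# stack of 3x3 valid convolution + ReLU + 2x2 max-pool blocks; branch
# outputs are flattened, concatenated, passed through a ReLU dense layer
# and a softmax head. Trained with Adam on categorical cross-entropy
# with early stopping on a held-out validation split. Implemented in
# base R matrix algebra (im2col convolutions); adequate for the compact
# image sizes used here, not for GPU-scale work.

#' CNN architecture specification
#'
#' @param branches list of input shapes, each `c(height, width)` =
#'   (time frames, frequency bins) of one image input.
#' @param filters convolution filters per block (one block per entry).
#' @param dense width of the dense layer before the softmax head.
#' @param nClasses number of output classes.
#' @return object of class `CNNSpec`.
#' @examples
#' cnnSpec(list(c(247, 257), c(247, 64)), nClasses = 3)
#' @export
cnnSpec <- function(branches, filters = c(16, 32, 64), dense = 64,
                    nClasses = 3) {
  if (!length(branches)) stop("need at least one input branch")
  branches <- lapply(branches, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || any(b < 1L)) stop("branch shapes are c(h, w)")
    b
  })
  # every block needs >= 3x3 input for the convolution and >= 2x2 to pool
  for (b in branches) {
    h <- b[1]
    w <- b[2]
    for (f in filters) {
      if (h < 3L || w < 3L) stop("image too small for the conv stack")
      h <- (h - 2L) %/% 2L
      w <- (w - 2L) %/% 2L
    }
    if (h < 1L || w < 1L) stop("image too small for the conv stack")
  }
  structure(
    list(
      branches = branches, filters = as.integer(filters),
      dense = as.integer(dense), nClasses = as.integer(nClasses)
    ),
    class = "CNNSpec"
  )
}

#' CNN training protocol
#'
#' Canonical protocol: 30 epochs, batch 16, learning rate 0.001 (Adam),
#' early stopping after 10 consecutive epochs without validation-loss
#' improvement, validating on 25% of the training set; the
#' best-validation-loss weights are restored.
#'
#' @param epochs maximum epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param validationFraction held-out fraction.
#' @param seed integer seed controlling init, shuffling and the split.
#' @return object of class `TrainProtocol`.
#' @export
trainProtocol <- function(epochs = 30, batch = 16, lr = 0.001,
                          patience = 10, validationFraction = 0.25,
                          seed = 1) {
  stopifnot(
    patience < epochs, validationFraction > 0, validationFraction < 1,
    batch >= 1, lr > 0
  )
  structure(
    list(
      epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
      patience = as.integer(patience),
      validationFraction = validationFraction, seed = seed
    ),
    class = "TrainProtocol"
  )
}

heInit <- function(nIn, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / nIn)), dim = dims)
}

#' Build an untrained CNN
#'
#' Initializes all parameters (He-normal) deterministically from `seed`.
#'
#' @param spec a [cnnSpec()].
#' @param seed integer seed.
#' @return object of class `CNNModel`.
#' @export
buildCnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "CNNSpec"))
  withSeed(seed, {
    params <- list()
    flatTotal <- 0L
    for (bi in seq_along(spec$branches)) {
      h <- spec$branches[[bi]][1]
      w <- spec$branches[[bi]][2]
      cIn <- 1L
      for (li in seq_along(spec$filters)) {
        f <- spec$filters[li]
        params[[sprintf("K%d_%d", bi, li)]] <-
          matrix(heInit(9 * cIn, c(9 * cIn, f)), 9 * cIn, f)
        params[[sprintf("kb%d_%d", bi, li)]] <- rep(0, f)
        h <- (h - 2L) %/% 2L
        w <- (w - 2L) %/% 2L
        cIn <- f
      }
      flatTotal <- flatTotal + h * w * cIn
    }
    params$W1 <- matrix(
      heInit(flatTotal, c(flatTotal, spec$dense)), flatTotal, spec$dense
    )
    params$b1 <- rep(0, spec$dense)
    params$W2 <- matrix(
      heInit(spec$dense, c(spec$dense, spec$nClasses)),
      spec$dense, spec$nClasses
    )
    params$b2 <- rep(0, spec$nClasses)
    structure(
      list(spec = spec, params = params, classes = NULL, history = NULL),
      class = "CNNModel"
    )
  })
}

#' @export
print.CNNModel <- function(x, ...) {
  nPar <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "CNNModel: %d branch(es), blocks [%s], dense %d, %d classes; %d parameters%s\n",
    length(x$spec$branches), paste(x$spec$filters, collapse = ", "),
    x$spec$dense, x$spec$nClasses, nPar,
    if (is.null(x$classes)) " (untrained)" else " (trained)"
  ))
  invisible(x)
}

# ---- layer primitives (batch-first arrays: B x H x W x C) -----------------

convForward <- function(x, k, bias) {
  d <- dim(x)
  b <- d[1]
  h <- d[2]
  w <- d[3]
  cIn <- d[4]
  oh <- h - 2L
  ow <- w - 2L
  cols <- matrix(0, b * oh * ow, 9L * cIn)
  colIdx <- 1L
  for (c in seq_len(cIn)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        cols[, colIdx] <- as.vector(
          x[, (1L + di):(oh + di), (1L + dj):(ow + dj), c]
        )
        colIdx <- colIdx + 1L
      }
    }
  }
  y <- cols %*% k
  y <- sweep(y, 2L, bias, "+")
  list(
    out = array(y, dim = c(b, oh, ow, ncol(k))),
    cols = cols, inDim = d
  )
}

convBackward <- function(cache, k, dOut) {
  d <- dim(dOut)
  dMat <- matrix(dOut, prod(d[1:3]), d[4])
  dK <- crossprod(cache$cols, dMat)
  dB <- colSums(dMat)
  dCols <- dMat %*% t(k)
  inDim <- cache$inDim
  b <- inDim[1]
  oh <- d[2]
  ow <- d[3]
  dX <- array(0, dim = inDim)
  colIdx <- 1L
  for (c in seq_len(inDim[4])) {
    for (dj in 0:2) {
      for (di in 0:2) {
        dX[, (1L + di):(oh + di), (1L + dj):(ow + dj), c] <-
          dX[, (1L + di):(oh + di), (1L + dj):(ow + dj), c] +
          array(dCols[, colIdx], dim = c(b, oh, ow))
        colIdx <- colIdx + 1L
      }
    }
  }
  list(dX = dX, dK = dK, dB = dB)
}

poolForward <- function(x) {
  d <- dim(x)
  oh <- d[2] %/% 2L
  ow <- d[3] %/% 2L
  i1 <- seq_len(oh) * 2L - 1L
  j1 <- seq_len(ow) * 2L - 1L
  s11 <- x[, i1, j1, , drop = FALSE]
  s21 <- x[, i1 + 1L, j1, , drop = FALSE]
  s12 <- x[, i1, j1 + 1L, , drop = FALSE]
  s22 <- x[, i1 + 1L, j1 + 1L, , drop = FALSE]
  out <- pmax(s11, s21, s12, s22)
  # first matching slice wins on ties
  which <- array(1L, dim = dim(out))
  which[out == s21 & out != s11] <- 2L
  which[out == s12 & out != s11 & out != s21] <- 3L
  which[out == s22 & out != s11 & out != s21 & out != s12] <- 4L
  list(out = out, which = which, inDim = d, i1 = i1, j1 = j1)
}

poolBackward <- function(cache, dOut) {
  dX <- array(0, dim = cache$inDim)
  i1 <- cache$i1
  j1 <- cache$j1
  put <- function(sel, ii, jj) {
    tmp <- dOut
    tmp[!sel] <- 0
    dX[, ii, jj, ] <<- dX[, ii, jj, , drop = FALSE] + tmp
  }
  put(cache$which == 1L, i1, j1)
  put(cache$which == 2L, i1 + 1L, j1)
  put(cache$which == 3L, i1, j1 + 1L)
  put(cache$which == 4L, i1 + 1L, j1 + 1L)
  dX
}

cnnForward <- function(model, xs, training = FALSE) {
  spec <- model$spec
  p <- model$params
  caches <- list()
  flats <- list()
  for (bi in seq_along(spec$branches)) {
    a <- xs[[bi]]
    for (li in seq_along(spec$filters)) {
      cv <- convForward(
        a, p[[sprintf("K%d_%d", bi, li)]], p[[sprintf("kb%d_%d", bi, li)]]
      )
      r <- pmax(cv$out, 0)
      pl <- poolForward(r)
      caches[[sprintf("b%d_l%d", bi, li)]] <- list(
        conv = cv, relu = cv$out > 0, pool = pl
      )
      a <- pl$out
    }
    d <- dim(a)
    flats[[bi]] <- matrix(a, d[1], prod(d[2:4]))
    caches[[sprintf("shape%d", bi)]] <- d
  }
  flat <- do.call(cbind, flats)
  z1 <- sweep(flat %*% p$W1, 2L, p$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% p$W2, 2L, p$b2, "+")
  m <- apply(z2, 1L, max)
  e <- exp(z2 - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs)
  if (training) {
    out$caches <- caches
    out$flat <- flat
    out$a1 <- a1
    out$z1 <- z1
  }
  out
}

cnnBackward <- function(model, fw, xs, yOneHot) {
  spec <- model$spec
  p <- model$params
  b <- nrow(yOneHot)
  grads <- list()
  dZ2 <- (fw$probs - yOneHot) / b
  grads$W2 <- crossprod(fw$a1, dZ2)
  grads$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(p$W2)
  dZ1 <- dA1 * (fw$z1 > 0)
  grads$W1 <- crossprod(fw$flat, dZ1)
  grads$b1 <- colSums(dZ1)
  dFlat <- dZ1 %*% t(p$W1)
  offset <- 0L
  for (bi in seq_along(spec$branches)) {
    d <- fw$caches[[sprintf("shape%d", bi)]]
    len <- prod(d[2:4])
    dA <- array(dFlat[, offset + seq_len(len), drop = FALSE], dim = d)
    offset <- offset + len
    for (li in rev(seq_along(spec$filters))) {
      cache <- fw$caches[[sprintf("b%d_l%d", bi, li)]]
      dRelu <- poolBackward(cache$pool, dA)
      dConv <- dRelu * cache$relu
      back <- convBackward(
        cache$conv, p[[sprintf("K%d_%d", bi, li)]], dConv
      )
      grads[[sprintf("K%d_%d", bi, li)]] <- back$dK
      grads[[sprintf("kb%d_%d", bi, li)]] <- back$dB
      dA <- back$dX
    }
  }
  grads
}

# Slice a list of branch arrays by sample index.
sliceBranches <- function(xs, idx) {
  lapply(xs, function(a) a[idx, , , , drop = FALSE])
}

crossEntropy <- function(probs, yOneHot) {
  -mean(log(pmax(rowSums(probs * yOneHot), 1e-12)))
}

#' Train a CNN
#'
#' Adam on categorical cross-entropy under the given protocol; stops
#' early after `patience` consecutive epochs without validation-loss
#' improvement and restores the best-validation-loss parameters.
#'
#' @param model a [buildCnn()] result.
#' @param xs list of branch inputs, each an array
#'   `(samples, height, width, 1)`; see [stackImages()].
#' @param y class labels.
#' @param protocol a [trainProtocol()].
#' @return trained `CNNModel` with a `history` data.frame (per-epoch
#'   train/validation losses).
#' @export
trainCnn <- function(model, xs, y, protocol = trainProtocol()) {
  stopifnot(inherits(model, "CNNModel"), inherits(protocol, "TrainProtocol"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least two classes")
  n <- dim(xs[[1]])[1]
  if (n <= protocol$batch) stop("dataset must exceed one batch")
  if (nlevels(y) != model$spec$nClasses) {
    stop("label count does not match the model head")
  }
  yIdx <- as.integer(y)
  oneHot <- diag(model$spec$nClasses)[yIdx, , drop = FALSE]
  withSeed(protocol$seed, {
    valIdx <- unlist(lapply(levels(y), function(cl) {
      pool <- which(y == cl)
      sample(pool, max(1L, round(protocol$validationFraction * length(pool))))
    }))
    trIdx <- setdiff(seq_len(n), valIdx)
    xsVal <- sliceBranches(xs, valIdx)
    yVal <- oneHot[valIdx, , drop = FALSE]
    mState <- lapply(model$params, function(p) p * 0)
    vState <- lapply(model$params, function(p) p * 0)
    beta1 <- 0.9
    beta2 <- 0.999
    step <- 0L
    best <- Inf
    bestParams <- model$params
    bad <- 0L
    history <- data.frame()
    for (epoch in seq_len(protocol$epochs)) {
      ord <- sample(trIdx)
      trainLoss <- 0
      nBatches <- 0L
      for (start in seq(1L, length(ord), by = protocol$batch)) {
        idx <- ord[start:min(start + protocol$batch - 1L, length(ord))]
        if (length(idx) < 2L) next
        xb <- sliceBranches(xs, idx)
        yb <- oneHot[idx, , drop = FALSE]
        fw <- cnnForward(model, xb, training = TRUE)
        grads <- cnnBackward(model, fw, xb, yb)
        step <- step + 1L
        for (nm in names(grads)) {
          g <- grads[[nm]]
          mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * g
          vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * g^2
          mHat <- mState[[nm]] / (1 - beta1^step)
          vHat <- vState[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            protocol$lr * mHat / (sqrt(vHat) + 1e-8)
        }
        trainLoss <- trainLoss + crossEntropy(fw$probs, yb)
        nBatches <- nBatches + 1L
      }
      valLoss <- crossEntropy(cnnForward(model, xsVal)$probs, yVal)
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = trainLoss / max(1L, nBatches),
        valLoss = valLoss
      ))
      if (valLoss < best - 1e-9) {
        best <- valLoss
        bestParams <- model$params
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= protocol$patience) break
      }
    }
    model$params <- bestParams
    model$classes <- levels(y)
    model$history <- history
    model
  })
}

#' Predict with a CNN
#'
#' @param model a trained `CNNModel`.
#' @param xs list of branch input arrays (see [stackImages()]).
#' @return list with `labels` (ties broken toward the lowest class
#'   index) and `probs` (rows sum to 1).
#' @export
predictCnn <- function(model, xs) {
  stopifnot(inherits(model, "CNNModel"))
  for (bi in seq_along(model$spec$branches)) {
    d <- dim(xs[[bi]])
    if (!all(d[2:3] == model$spec$branches[[bi]])) {
      stop("input shape does not match the model spec")
    }
  }
  if (dim(xs[[1]])[1] == 0L) {
    return(list(
      labels = factor(character(), levels = model$classes),
      probs = matrix(0, 0, model$spec$nClasses)
    ))
  }
  probs <- cnnForward(model, xs)$probs
  cls <- model$classes
  if (is.null(cls)) cls <- as.character(seq_len(model$spec$nClasses))
  colnames(probs) <- cls
  list(
    labels = factor(cls[max.col(probs, ties.method = "first")], levels = cls),
    probs = probs
  )
}

#' Stack time-frequency images into a CNN input array
#'
#' Converts a list of [TFImage-class] objects (frequency x time) into a
#' `(samples, time, frequency, 1)` array, matching the
#' (channel, time, frequency) image convention.
#'
#' @param images list of [TFImage-class] with identical shapes.
#' @return 4-d array.
#' @export
stackImages <- function(images) {
  stopifnot(length(images) > 0L)
  d <- dim(images[[1]])
  out <- array(0, dim = c(length(images), d[2], d[1], 1L))
  for (i in seq_along(images)) {
    out[i, , , 1L] <- t(tfValues(images[[i]]))
  }
  out
}
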