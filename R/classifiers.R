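# Classical classifiers (regularized LDA, SVM-RBF, RUSBoost) behind one
# train/predict surface, plus seeded sequential model-based hyperparameter
# optimization (Gaussian-process surrogate, expected-improvement
# acquisition) against a stratified validation split.

#' Hyperparameter search spaces
#'
#' Named ranges per classifier: `delta` (covariance shrinkage) for LDA;
#' `cost` (box constraint) and `kernelScale` for the RBF SVM; `learnRate`,
#' `varsToSample`, `nCycles` (learning cycles), `minLeaf` and `maxSplits`
#' for RUSBoost. Ranges spanning decades are searched in log scale.
#'
#' @param kind `"lda"`, `"svm_rbf"` or `"rusboost"`.
#' @return list of parameter descriptors (`lower`, `upper`, `log`,
#'   `integer`).
#' @export
defaultHyperparamSpace <- function(kind) {
  switch(kind,
    lda = list(
      delta = list(lower = 1e-6, upper = 1, log = TRUE, integer = FALSE)
    ),
    svm_rbf = list(
      cost = list(lower = 1e-3, upper = 1e3, log = TRUE, integer = FALSE),
      kernelScale = list(
        lower = 1e-3, upper = 1e3, log = TRUE, integer = FALSE
      )
    ),
    rusboost = list(
      learnRate = list(lower = 1e-3, upper = 1, log = TRUE, integer = FALSE),
      varsToSample = list(lower = 0.1, upper = 1, log = FALSE, integer = FALSE),
      nCycles = list(lower = 10, upper = 500, log = FALSE, integer = TRUE),
      minLeaf = list(lower = 1, upper = 50, log = FALSE, integer = TRUE),
      maxSplits = list(lower = 1, upper = 1024, log = TRUE, integer = TRUE)
    ),
    stop("unknown classifier kind: ", kind)
  )
}

# ---- regularized Gaussian LDA --------------------------------------------

# Pooled-covariance LDA with shrinkage toward the average variance:
# Sigma(delta) = (1 - delta) * Sigma_pooled + delta * mean(diag(Sigma)) * I.
fitLda <- function(x, y, delta = 1e-4) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  p <- ncol(x)
  means <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
    numeric(p)
  ))
  centered <- x - means[as.integer(y), , drop = FALSE]
  pooled <- crossprod(centered) / max(1L, nrow(x) - length(classes))
  shrink <- (1 - delta) * pooled +
    (delta * mean(diag(pooled)) + 1e-8) * diag(p)
  inv <- solve(shrink)
  priors <- as.numeric(table(y)[classes]) / length(y)
  list(
    classes = classes, means = means, inv = inv, priors = priors,
    delta = delta
  )
}

predictLda <- function(model, x) {
  x <- as.matrix(x)
  scores <- vapply(seq_along(model$classes), function(k) {
    mu <- model$means[k, ]
    drop(x %*% (model$inv %*% mu)) -
      0.5 * drop(t(mu) %*% model$inv %*% mu) + log(model$priors[k])
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(x))
  # softmax over discriminants for probability-like scores
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  probs <- e / rowSums(e)
  colnames(probs) <- model$classes
  list(
    labels = factor(model$classes[max.col(scores, ties.method = "first")],
      levels = model$classes
    ),
    probs = probs
  )
}

# ---- RUSBoost -------------------------------------------------------------

# Boosted shallow trees (SAMME) where each round's training subset is
# rebalanced by randomly undersampling every class to the minority-class
# count, weighted by the current boosting weights.
fitRusboost <- function(x, y, nCycles = 50, learnRate = 0.1, minLeaf = 5,
                        maxSplits = 16, varsToSample = 1) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  kk <- length(classes)
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  roundClassCounts <- list()
  minCount <- min(table(y))
  depth <- max(1L, ceiling(log2(maxSplits + 1)))
  for (m in seq_len(nCycles)) {
    idx <- unlist(lapply(classes, function(cl) {
      pool <- which(y == cl)
      if (length(pool) == 1L) {
        return(pool)
      }
      sample(pool, minCount,
        replace = length(pool) < minCount,
        prob = w[pool] / sum(w[pool])
      )
    }))
    roundClassCounts[[m]] <- table(y[idx])
    nVars <- max(1L, round(varsToSample * ncol(x)))
    vars <- if (nVars < ncol(x)) sample(ncol(x), nVars) else seq_len(ncol(x))
    df <- x[idx, vars, drop = FALSE]
    df$.y <- y[idx]
    tree <- rpart::rpart(.y ~ ., df,
      method = "class",
      control = rpart::rpart.control(
        minbucket = minLeaf, maxdepth = min(30L, depth), cp = 0,
        xval = 0, maxcompete = 0, maxsurrogate = 0
      )
    )
    pred <- factor(
      as.character(predict(tree, x[, vars, drop = FALSE], type = "class")),
      levels = classes
    )
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / kk || err <= 0) {
      if (err <= 0) {
        learners[[length(learners) + 1L]] <- list(tree = tree, vars = vars)
        alphas <- c(alphas, 1)
      }
      break
    }
    alpha <- learnRate * (log((1 - err) / err) + log(kk - 1))
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- list(tree = tree, vars = vars)
    alphas <- c(alphas, alpha)
  }
  list(
    classes = classes, learners = learners, alphas = alphas,
    roundClassCounts = roundClassCounts
  )
}

predictRusboost <- function(model, x) {
  x <- as.data.frame(x)
  classes <- model$classes
  votes <- matrix(0, nrow(x), length(classes),
    dimnames = list(NULL, classes)
  )
  for (i in seq_along(model$learners)) {
    lr <- model$learners[[i]]
    pr <- predict(lr$tree, x[, lr$vars, drop = FALSE], type = "class")
    pr <- factor(as.character(pr), levels = classes)
    votes[cbind(seq_len(nrow(x)), as.integer(pr))] <-
      votes[cbind(seq_len(nrow(x)), as.integer(pr))] + model$alphas[i]
  }
  probs <- votes / pmax(rowSums(votes), EPS)
  list(
    labels = factor(classes[max.col(votes, ties.method = "first")],
      levels = classes
    ),
    probs = probs
  )
}

# ---- unified train / predict ---------------------------------------------

trainClassifier <- function(kind, x, y, config) {
  y <- droplevels(as.factor(y))
  scaling <- NULL
  model <- switch(kind,
    lda = fitLda(x, y, delta = config$delta),
    svm_rbf = {
      xm <- as.matrix(x)
      ctr <- colMeans(xm)
      scl <- apply(xm, 2L, stats::sd)
      scl[scl < EPS] <- 1
      scaling <- list(center = ctr, scale = scl)
      e1071::svm(
        sweep(sweep(xm, 2L, ctr), 2L, scl, "/"), y,
        kernel = "radial", scale = FALSE,
        cost = config$cost, gamma = 1 / (2 * config$kernelScale^2),
        probability = TRUE
      )
    },
    rusboost = fitRusboost(
      x, y,
      nCycles = config$nCycles, learnRate = config$learnRate,
      minLeaf = config$minLeaf, maxSplits = config$maxSplits,
      varsToSample = config$varsToSample
    ),
    duration = {
      df <- data.frame(duration = x[, 1], .y = y)
      rpart::rpart(.y ~ duration, df,
        method = "class",
        control = rpart::rpart.control(cp = 0, xval = 0, minbucket = 2)
      )
    },
    stop("unknown classifier kind: ", kind)
  )
  structure(
    list(kind = kind, model = model, config = config,
         channels = colnames(x), classes = levels(y), scaling = scaling),
    class = "ArsClassifier"
  )
}

#' Predict event classes
#'
#' One label per row plus per-class scores (probabilities summing to 1)
#' where the underlying model provides them.
#'
#' @param object a trained classifier from [optimizeAndFit()].
#' @param x feature matrix with the training channel set.
#' @param ... unused.
#' @return list with `labels` (factor) and `probs` (matrix).
#' @export
predict.ArsClassifier <- function(object, x, ...) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) {
    return(list(
      labels = factor(character(), levels = object$classes),
      probs = matrix(0, 0, length(object$classes),
        dimnames = list(NULL, object$classes)
      )
    ))
  }
  if (!is.null(object$channels) && !is.null(colnames(x))) {
    if (!all(object$channels %in% colnames(x))) {
      stop("feature channels do not match the training channel set")
    }
    x <- x[, object$channels, drop = FALSE]
  } else if (ncol(x) != length(object$channels)) {
    stop("feature channels do not match the training channel set")
  }
  switch(object$kind,
    lda = predictLda(object$model, x),
    svm_rbf = {
      x <- sweep(sweep(x, 2L, object$scaling$center), 2L,
        object$scaling$scale, "/"
      )
      pr <- predict(object$model, x, probability = TRUE)
      probs <- attr(pr, "probabilities")
      probs <- probs[, object$classes, drop = FALSE]
      list(
        labels = factor(as.character(pr), levels = object$classes),
        probs = probs
      )
    },
    rusboost = predictRusboost(object$model, x),
    duration = {
      probs <- predict(object$model, data.frame(duration = x[, 1]),
        type = "prob"
      )
      cls <- colnames(probs)
      list(
        labels = factor(cls[max.col(probs, ties.method = "first")],
          levels = object$classes
        ),
        probs = probs
      )
    }
  )
}

#' @export
print.ArsClassifier <- function(x, ...) {
  cat(sprintf(
    "ArsClassifier '%s' over %d channel(s), classes: %s\n",
    x$kind, length(x$channels), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

# ---- sequential model-based optimization ---------------------------------

# Map unit-cube coordinates to the parameter space.
decodeParams <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    d <- space[[j]]
    v <- if (d$log) {
      exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
    } else {
      d$lower + u[j] * (d$upper - d$lower)
    }
    if (d$integer) v <- as.integer(round(v))
    out[[names(space)[j]]] <- v
  }
  out
}

# GP posterior (RBF kernel + nugget) over observed unit-cube points.
gpPosterior <- function(U, yv, Unew, lengthScale = 0.3, nugget = 1e-4) {
  k <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    exp(-pmax(d2, 0) / (2 * lengthScale^2))
  }
  kxx <- k(U, U) + diag(nugget, nrow(U))
  kxs <- k(U, Unew)
  mu0 <- mean(yv)
  alpha <- solve(kxx, yv - mu0)
  mu <- mu0 + drop(t(kxs) %*% alpha)
  kinv <- solve(kxx)
  var <- pmax(1 - colSums(kxs * (kinv %*% kxs)), 1e-10)
  list(mean = mu, sd = sqrt(var))
}

#' Tune and fit a classifier with sequential model-based optimization
#'
#' Splits the training data into a stratified 75/25 train/validation
#' split, searches the hyperparameter space by expected improvement over
#' a Gaussian-process surrogate (Latin-hypercube initial design), and
#' refits the winning configuration on the full training set. Fully
#' reproducible from `(data, seed)`.
#'
#' @param kind `"lda"`, `"svm_rbf"` or `"rusboost"`.
#' @param x feature matrix (samples x channels, named columns).
#' @param y class labels.
#' @param space parameter space (see [defaultHyperparamSpace()]).
#' @param budget total objective evaluations (>= 1).
#' @param seed integer seed.
#' @param validationFraction held-out fraction for the tuning objective.
#' @return an `ArsClassifier` with attributes `chosenConfig` and
#'   `searchHistory`.
#' @export
optimizeAndFit <- function(kind, x, y, space = defaultHyperparamSpace(kind),
                           budget = 30, seed = 1,
                           validationFraction = 0.25) {
  if (budget < 1L) stop("budget must be at least 1")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (min(table(y)) < 2L) stop("need at least two samples per class")
  d <- length(space)
  withSeed(seed, {
    # stratified validation split
    valIdx <- unlist(lapply(levels(y), function(cl) {
      pool <- which(y == cl)
      sample(pool, max(1L, round(validationFraction * length(pool))))
    }))
    trIdx <- setdiff(seq_len(nrow(x)), valIdx)
    objective <- function(u) {
      cfg <- decodeParams(u, space)
      m <- tryCatch(
        trainClassifier(kind, x[trIdx, , drop = FALSE], y[trIdx], cfg),
        error = function(e) NULL
      )
      if (is.null(m)) {
        return(0)
      }
      pred <- predict(m, x[valIdx, , drop = FALSE])
      mean(pred$labels == y[valIdx])
    }
    nInit <- min(max(2L, ceiling(budget / 3)), budget)
    U <- as.matrix(lhs::randomLHS(nInit, d))
    yv <- apply(U, 1L, objective)
    while (nrow(U) < budget) {
      cand <- matrix(stats::runif(256 * d), ncol = d)
      post <- gpPosterior(U, yv, cand)
      best <- max(yv)
      z <- (post$mean - best - 1e-3) / post$sd
      ei <- post$sd * (z * stats::pnorm(z) + stats::dnorm(z))
      u <- cand[which.max(ei), , drop = FALSE]
      U <- rbind(U, u)
      yv <- c(yv, objective(drop(u)))
    }
    bestU <- U[which.max(yv), ]
    cfg <- decodeParams(bestU, space)
    model <- trainClassifier(kind, x, y, cfg)
    attr(model, "chosenConfig") <- cfg
    attr(model, "searchHistory") <- data.frame(
      eval = seq_along(yv), validationAccuracy = yv
    )
    attr(model, "seed") <- seed
    model
  })
}
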