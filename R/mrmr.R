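# Minimum redundancy maximum relevance (MRMR) feature ranking with the
# mutual-information-quotient (MIQ) criterion: the first feature maximizes
# I(f; y); each subsequent pick maximizes relevance / mean redundancy,
# I(f; y) / mean_{s in selected} I(f; s). Continuous features are
# discretized into equal-frequency bins before mutual information
# estimation.

# Equal-frequency discretization into `bins` integer codes 1..bins.
discretizeEqualFreq <- function(x, bins = 10L) {
  if (length(unique(x)) <= bins) {
    return(match(x, sort(unique(x))))
  }
  q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
    type = 7, names = FALSE
  ))
  codes <- findInterval(x, q, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(codes)
}

# Mutual information (nats) between two integer code vectors.
miDiscrete <- function(a, b) {
  n <- length(a)
  ka <- max(a)
  kb <- max(b)
  joint <- tabulate((a - 1L) * kb + b, nbins = ka * kb) / n
  pa <- tabulate(a, nbins = ka) / n
  pb <- tabulate(b, nbins = kb) / n
  # joint is laid out a-major (index (a-1)*kb + b), so b varies fastest
  outer_p <- as.vector(t(outer(pa, pb)))
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer_p[pos]))
}

# MI of every column of integer code matrix D against code vector s,
# vectorized over features.
miAgainstAll <- function(D, s, bins) {
  n <- nrow(D)
  ks <- max(s)
  ps <- tabulate(s, nbins = ks) / n
  # column marginals
  pf <- vapply(seq_len(bins), function(b) colSums(D == b), numeric(ncol(D)))
  if (is.null(dim(pf))) pf <- matrix(pf, nrow = ncol(D))
  pf <- pf / n
  mi <- numeric(ncol(D))
  for (b in seq_len(ks)) {
    rows <- s == b
    if (!any(rows)) next
    Db <- D[rows, , drop = FALSE]
    for (a in seq_len(bins)) {
      pj <- colSums(Db == a) / n
      pe <- pf[, a] * ps[b]
      pos <- pj > 0 & pe > 0
      mi[pos] <- mi[pos] + pj[pos] * log(pj[pos] / pe[pos])
    }
  }
  mi
}

#' MRMR-MIQ feature ranking
#'
#' Greedy mutual-information-quotient ranking of feature columns against
#' a class label. Ranks up to `maxRank` features (all by default);
#' remaining features are appended in relevance order so the result is
#' always a permutation of all columns.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels (factor or coercible).
#' @param bins equal-frequency discretization bins.
#' @param maxRank greedy steps to run (ranking beyond it falls back to
#'   relevance order).
#' @return object of class `FeatureRanking`: list with `order` (column
#'   indices), `scores` (MIQ score per rank) and `relevance`.
#' @export
mrmrRank <- function(x, y, bins = 10L, maxRank = ncol(x)) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need at least two classes")
  if (ncol(x) < 1L) stop("need at least one feature")
  nAll <- ncol(x)
  maxRank <- min(maxRank, nAll)
  D <- vapply(
    seq_len(nAll), function(j) discretizeEqualFreq(x[, j], bins),
    integer(nrow(x))
  )
  yy <- as.integer(droplevels(y))
  relevance <- miAgainstAll(D, yy, bins)
  selected <- integer(0)
  scores <- numeric(0)
  redSum <- numeric(nAll)
  remaining <- seq_len(nAll)
  for (step in seq_len(maxRank)) {
    if (step == 1L) {
      crit <- relevance[remaining]
    } else {
      meanRed <- redSum[remaining] / length(selected)
      crit <- relevance[remaining] / pmax(meanRed, EPS)
    }
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (!length(remaining)) break
    redSum[remaining] <- redSum[remaining] +
      miAgainstAll(D[, remaining, drop = FALSE], D[, pick], bins)
  }
  if (length(remaining)) {
    rest <- remaining[order(relevance[remaining], decreasing = TRUE)]
    selected <- c(selected, rest)
    scores <- c(scores, relevance[rest])
  }
  structure(
    list(order = selected, scores = scores, relevance = relevance),
    class = "FeatureRanking"
  )
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat(sprintf(
    "MRMR-MIQ ranking of %d features; top 5: %s\n",
    length(x$order), paste(utils::head(x$order, 5L), collapse = ", ")
  ))
  invisible(x)
}

#' Select the top-k features from a ranking
#'
#' Order-preserving prefix of the ranking; selections are nested
#' (top 10 is a subset of top 100).
#'
#' @param ranking a [mrmrRank()] result.
#' @param k number of features, or `"all"`.
#' @return integer vector of column indices.
#' @export
selectSubset <- function(ranking, k) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  if (identical(k, "all")) {
    return(ranking$order)
  }
  k <- as.integer(k)
  if (k < 1L || k > length(ranking$order)) {
    stop("k out of range")
  }
  ranking$order[seq_len(k)]
}
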