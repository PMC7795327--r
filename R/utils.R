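# Internal helpers shared across modules.

# Event label vocabulary. other50/other150 are the fixed-duration negative
# classes; otherCrackle/otherWheeze the Burr variable-duration negatives.
EVENT_LABELS <- c(
  "crackle", "wheeze", "other50", "other150", "otherCrackle", "otherWheeze"
)

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Per-recording random streams are derived from one master seed and the
#' recording identifier with a small polynomial string hash, so that a
#' corpus is reproducible as a whole while each file gets its own
#' predetermined stream.
#'
#' @param seed master seed (integer).
#' @param ... character components mixed into the hash.
#' @return an integer in \[0, 2^31 - 2\].
#' @examples
#' deriveSeed(1, "p1_r1")
#' @export
deriveSeed <- function(seed, ...) {
  key <- paste(c(as.character(seed), unlist(list(...))), collapse = "/")
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  h <- as.numeric(seed %% m)
  for (cp in utf8ToInt(key)) {
    h <- (h * 131 + cp) %% m
  }
  as.integer(h)
}

# Run expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Validate an event data.frame (columns start, end, label).
checkEvents <- function(events, allowEmpty = TRUE) {
  stopifnot(is.data.frame(events))
  needed <- c("start", "end", "label")
  if (!all(needed %in% names(events))) {
    stop("event table must have columns start, end, label")
  }
  if (nrow(events) == 0L) {
    if (!allowEmpty) stop("event table is empty")
    return(invisible(events))
  }
  if (any(!is.finite(events$start)) || any(!is.finite(events$end))) {
    stop("event times must be finite")
  }
  if (any(events$start < 0) || any(events$end <= events$start)) {
    stop("events must satisfy 0 <= start < end")
  }
  bad <- setdiff(unique(as.character(events$label)), EVENT_LABELS)
  if (length(bad)) {
    stop("unknown event label(s): ", paste(bad, collapse = ", "))
  }
  invisible(events)
}

emptyEvents <- function() {
  data.frame(
    start = numeric(), end = numeric(), label = character(),
    stringsAsFactors = FALSE
  )
}

# Half-open [start, end) interval to sample indices: floor start down,
# ceil end up, so no sample is silently dropped.
eventSampleRange <- function(start, end, rate) {
  i0 <- floor(start * rate) + 1
  i1 <- ceiling(end * rate)
  c(as.integer(i0), as.integer(max(i1, i0)))
}
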