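# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so library calls never clobber a caller's
#' stream. A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up to `digits`; base round() is half-even and would print
# 0.5-boundary percentages differently from the conventional reading
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Euclidean distance matrix between two point sets given as two-column
# matrices; plain outer-product arithmetic, no dependency on dist().
cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Nearest-neighbour distance for each row of `a` against `b`.
# `exclude_self = TRUE` treats a and b as the same set and ignores the
# zero self-distance. Chunked so that 1e4-point sets stay within memory.
nn_dist_chunked <- function(a, b, exclude_self = FALSE, chunk = 512L) {
  n <- nrow(a)
  out <- numeric(n)
  if (n == 0L) {
    return(out)
  }
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- cross_dist(a[idx, , drop = FALSE], b)
    if (exclude_self) {
      d[cbind(seq_along(idx), idx)] <- Inf
    }
    out[idx] <- apply(d, 1, min)
  }
  out
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
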