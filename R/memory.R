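#' Build a semi-tensor product associative memory
#'
#' Stores m distinct bipolar patterns of length n as canonical vectors of
#' dimension 2^n. Conceptually the memory is the 2^n x 2^n matrix
#' \deqn{L = \sum_{k=1}^m \delta_{2^n}^{r_k} (\delta_{2^n}^{r_k})^T,}
#' a 0/1 diagonal matrix with ones exactly at the stored indices, so every
#' stored pattern is an exact fixed point (L delta^r = delta^r). The matrix
#' is never materialized at scale: the object keeps the stored index set
#' plus a cache of lazily learned probabilistic columns, so memories with
#' n in the dozens are cheap. A dense form exists only as a small-n oracle
#' ([dense_memory_matrix()]).
#'
#' Association is controlled by the bit error control parameter `bec`
#' (E_c): a probe within Hamming distance E_c of at least one stored
#' pattern is classified by a probability distribution over the nearby
#' stored patterns (see [update_column()]). Learned columns are cached in
#' an environment inside the object, so recognition can learn on demand
#' without reassigning the memory; changing E_c with [set_bec()] clears
#' the cache, since every learned column is valid only for one E_c.
#'
#' @param modes a list of bipolar patterns (numeric vectors in \{-1,1\}^n),
#'   or a matrix with one pattern per row. All patterns must share one
#'   length and be pairwise distinct.
#' @param bec non-negative integer E_c, the maximum Hamming distance at
#'   which a corrupted probe may still be associated to a stored pattern.
#'   `bec = 0` disables association: only exact matches are recognized.
#' @return an object of class `stp_memory`.
#' @examples
#' mem <- stp_memory(list(c(1, 1, -1, 1, 1), c(1, -1, 1, -1, -1)), bec = 2)
#' stored_indices(mem)  # 5 12
#' @export
stp_memory <- function(modes, bec = 0) {
  if (is.matrix(modes)) modes <- lapply(seq_len(nrow(modes)), function(i) modes[i, ])
  if (!is.list(modes)) stop("`modes` must be a list of patterns or a matrix")
  check_bec(bec)
  n <- if (length(modes)) length(modes[[1]]) else 0L
  stored <- numeric(0)
  pat <- matrix(0, nrow = length(modes), ncol = n)
  for (k in seq_along(modes)) {
    x <- validate_bipolar(modes[[k]], sprintf("modes[[%d]]", k))
    if (length(x) != n)
      stop(sprintf("pattern %d has length %d, expected %d", k, length(x), n))
    r <- binary_to_index(bipolar_to_binary(x))
    if (r %in% stored)
      stop(sprintf("duplicate pattern at position %d (index %s)",
                   k, format(r, scientific = FALSE)))
    stored[k] <- r
    pat[k, ] <- bipolar_to_binary(x)
  }
  cache <- new.env(parent = emptyenv())
  cache$learned <- list()
  cache$bec <- bec
  structure(list(n = n, stored = stored, patterns = pat, cache = cache),
            class = "stp_memory")
}

check_bec <- function(bec) {
  if (length(bec) != 1L || is.na(bec) || bec < 0 || bec != floor(bec))
    stop("`bec` must be a non-negative integer")
}

#' @export
print.stp_memory <- function(x, ...) {
  cat(sprintf(
    "STP associative memory: n = %d, %d stored pattern(s), E_c = %s, %d learned column(s)\n",
    x$n, length(x$stored), format(x$cache$bec), length(x$cache$learned)))
  invisible(x)
}

#' Stored canonical-vector indices, in insertion order
#' @param mem an `stp_memory`.
#' @return numeric vector of 1-based indices into `1..2^n`.
#' @export
stored_indices <- function(mem) {
  stopifnot(inherits(mem, "stp_memory"))
  mem$stored
}

#' Bit error control parameter of a memory
#' @param mem an `stp_memory`.
#' @return the current E_c.
#' @export
get_bec <- function(mem) {
  stopifnot(inherits(mem, "stp_memory"))
  mem$cache$bec
}

#' Change the bit error control parameter
#'
#' Clears all learned columns: a learned column's probabilities depend on
#' which stored patterns fall inside the E_c ball, so cached columns are
#' valid for one E_c only.
#'
#' @param mem an `stp_memory` (modified in place via its cache environment).
#' @param bec new non-negative integer E_c.
#' @return the memory, invisibly.
#' @export
set_bec <- function(mem, bec) {
  stopifnot(inherits(mem, "stp_memory"))
  check_bec(bec)
  mem$cache$bec <- bec
  mem$cache$learned <- list()
  invisible(mem)
}

#' Probabilistic column constructor (internal)
#'
#' A sparse column of the memory matrix: either empty (a zero column) or a
#' probability distribution over stored indices. Probabilities come from
#' integer distance arithmetic, so exact numerators/denominators over a
#' common denominator are carried alongside the numeric values.
#'
#' @noRd
prob_column <- function(index = numeric(0), prob = numeric(0),
                        num = integer(0), den = integer(0)) {
  structure(list(index = index, prob = prob, num = num, den = den),
            class = "prob_column")
}

#' @export
print.prob_column <- function(x, ...) {
  if (!length(x$index)) {
    cat("zero column\n")
    return(invisible(x))
  }
  for (i in seq_along(x$index))
    cat(sprintf("  -> %s  p = %s (%d/%d)\n",
                format(x$index[i], scientific = FALSE),
                format(x$prob[i]), x$num[i], x$den[i]))
  invisible(x)
}

#' Test whether a probabilistic column is the zero column
#' @param col a `prob_column`.
#' @return `TRUE` if the column has empty support.
#' @export
is_zero_column <- function(col) length(col$index) == 0L

#' Column of the memory matrix
#'
#' Returns column r of the conceptual matrix L without building L: a point
#' mass on r itself if r is stored (the exact-recall fixed point), the
#' cached learned column if r was previously associated, and the zero
#' column otherwise. This is a pure lookup; it never triggers learning
#' (see [update_column()] and [recognize()] for that).
#'
#' @param mem an `stp_memory`.
#' @param r index in `1..2^n`.
#' @return a `prob_column`.
#' @export
memory_column <- function(mem, r) {
  stopifnot(inherits(mem, "stp_memory"))
  if (length(r) != 1L || is.na(r) || r != floor(r) || r < 1 || r > 2^mem$n)
    stop(sprintf("`r` must be an integer in 1..2^%d", mem$n))
  if (r %in% mem$stored)
    return(prob_column(index = r, prob = 1, num = 1L, den = 1L))
  key <- format(r, scientific = FALSE)
  if (!is.null(mem$cache$learned[[key]]))
    return(mem$cache$learned[[key]])
  prob_column()
}

#' Learn the column for an unrecognized probe (BEC update)
#'
#' For a probe index r_i not among the stored patterns, sets the transition
#' probability from the probe to each stored pattern k at Hamming distance
#' s_ki with 0 < s_ki <= E_c to
#' \deqn{l_{r_k r_i} = \frac{1/s_{ki}}{\sum_{j:\, 0 < s_{ji} \le E_c} 1/s_{ji}},}
#' i.e. inverse-distance weights normalized over the stored patterns inside
#' the E_c ball. Closer patterns get proportionally higher probability;
#' equal distances get equal probability. If no stored pattern lies within
#' E_c the column stays zero and is not cached, so a later E_c increase can
#' reconsider the probe. A nonzero result is cached in the memory.
#'
#' @param mem an `stp_memory`.
#' @param r_i probe index in `1..2^n`, not a stored index.
#' @return the learned `prob_column` (possibly zero).
#' @export
update_column <- function(mem, r_i) {
  stopifnot(inherits(mem, "stp_memory"))
  if (r_i %in% mem$stored)
    stop("probe index is a stored pattern; exact recognition applies")
  if (r_i != floor(r_i) || r_i < 1 || r_i > 2^mem$n)
    stop(sprintf("`r_i` must be an integer in 1..2^%d", mem$n))
  y <- index_to_binary(r_i, mem$n)
  s <- colSums(t(mem$patterns) != y)
  ec <- mem$cache$bec
  inside <- which(s > 0 & s <= ec)
  if (!length(inside)) return(prob_column())
  # exact rational weights: with D = lcm of the distances in the window,
  # p_k = (D / s_k) / sum_j (D / s_j); falls back to floating point when
  # the common denominator leaves exact integer range
  d <- Reduce(lcm_int, unique(s[inside]))
  num <- d / s[inside]
  den <- sum(num)
  if (is.finite(den) && den <= .Machine$integer.max) {
    g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), c(num, den))
    col <- prob_column(index = mem$stored[inside], prob = num / den,
                       num = as.integer(num / g),
                       den = rep(as.integer(den / g), length(inside)))
  } else {
    w <- 1 / s[inside]
    col <- prob_column(index = mem$stored[inside], prob = w / sum(w),
                       num = rep(NA_integer_, length(inside)),
                       den = rep(NA_integer_, length(inside)))
  }
  mem$cache$learned[[format(r_i, scientific = FALSE)]] <- col
  col
}

#' Recognize a pattern, learning on demand
#'
#' The full recognition procedure: encode the probe as delta_{2^n}^{r_i},
#' look up column r_i of the memory; if it is nonzero, classify by that
#' distribution (an exact point mass for a stored pattern). If zero, run
#' the BEC column update and re-check: a nonzero learned column classifies
#' the probe by association, otherwise the probe belongs to no stored
#' pattern and is rejected.
#'
#' @param mem an `stp_memory`.
#' @param x a bipolar pattern of length n.
#' @return an object of class `stp_recognition` with fields `status` (one
#'   of `"recognized_exact"`, `"classified_by_association"`, `"rejected"`),
#'   `distribution` (a `prob_column`), and `query_index`.
#' @examples
#' mem <- stp_memory(list(c(1, 1, -1, 1, 1), c(-1, -1, -1, 1, 1)), bec = 2)
#' recognize(mem, c(1, 1, -1, 1, 1))$status    # exact fixed point
#' recognize(mem, c(-1, 1, -1, 1, 1))$status   # associated within E_c
#' @export
recognize <- function(mem, x) {
  stopifnot(inherits(mem, "stp_memory"))
  x <- validate_bipolar(x)
  if (length(x) != mem$n)
    stop(sprintf("pattern has length %d, expected %d", length(x), mem$n))
  r <- encode_mode(x)$index
  col <- memory_column(mem, r)
  if (!is_zero_column(col)) {
    status <- if (r %in% mem$stored) "recognized_exact" else "classified_by_association"
    return(recognition_result(status, col, r))
  }
  col <- update_column(mem, r)
  if (!is_zero_column(col))
    return(recognition_result("classified_by_association", col, r))
  recognition_result("rejected", col, r)
}

recognition_result <- function(status, distribution, query_index) {
  structure(list(status = status, distribution = distribution,
                 query_index = query_index),
            class = "stp_recognition")
}

#' @export
print.stp_recognition <- function(x, ...) {
  cat(sprintf("query delta index %s: %s\n",
              format(x$query_index, scientific = FALSE), x$status))
  print(x$distribution)
  invisible(x)
}

#' Draw a hard class assignment from a recognition result
#'
#' The model returns a probability distribution over stored patterns; when
#' a single label is needed, one stored index is sampled from it with a
#' seeded generator. Deterministic given the seed; the caller's RNG state
#' is left untouched.
#'
#' @param result an `stp_recognition`, not rejected.
#' @param seed integer seed for the draw.
#' @return one stored index.
#' @export
classify_sample <- function(result, seed) {
  stopifnot(inherits(result, "stp_recognition"))
  if (result$status == "rejected")
    stop("cannot sample from a rejected recognition result")
  col <- result$distribution
  if (length(col$index) == 1L) return(col$index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  col$index[sample.int(length(col$index), 1L, prob = col$prob)]
}

#' Learn every column of the memory matrix
#'
#' Runs recognition (with caching) for all 2^n indices and returns the
#' full conceptual column map — the fully learned matrix, as in a state
#' transition diagram over all modes. Only sensible for small n; capped
#' because the result has 2^n entries.
#'
#' @param mem an `stp_memory`.
#' @param cap maximum n allowed (default 16).
#' @return a list of `prob_column`, one per index 1..2^n (zero columns for
#'   rejected modes).
#' @export
learn_all <- function(mem, cap = 16) {
  stopifnot(inherits(mem, "stp_memory"))
  if (mem$n > cap)
    stop(sprintf(
      "n = %d exceeds the cap (%d); query columns lazily with recognize()",
      mem$n, cap))
  N <- 2^mem$n
  out <- vector("list", N)
  for (r in seq_len(N)) {
    col <- memory_column(mem, r)
    if (is_zero_column(col) && !(r %in% mem$stored)) col <- update_column(mem, r)
    out[[r]] <- col
  }
  out
}

#' Dense memory matrix (small-n oracle)
#'
#' Materializes the full 2^n x 2^n matrix from [memory_column()]. Before
#' any update this is the Boolean diagonal matrix with ones at the stored
#' indices; learned columns add off-diagonal probability entries. Intended
#' as a test oracle, hence capped at n <= 8.
#'
#' @param mem an `stp_memory`.
#' @return a base matrix of dimension 2^n x 2^n.
#' @export
dense_memory_matrix <- function(mem) {
  stopifnot(inherits(mem, "stp_memory"))
  if (mem$n > 8) stop("dense memory matrix is capped at n <= 8")
  N <- 2^mem$n
  L <- matrix(0, N, N)
  for (r in seq_len(N)) {
    col <- memory_column(mem, r)
    if (!is_zero_column(col)) L[col$index, r] <- col$prob
  }
  L
}
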