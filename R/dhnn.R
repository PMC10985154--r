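#' Hebbian outer-product weight matrix
#'
#' Classical discrete Hopfield network (DHNN) storage rule:
#' \deqn{W = \alpha \sum_{k=1}^m (X^k (X^k)^T - I),}
#' for bipolar patterns X^k. Since every component squares to 1 the result
#' is symmetric with zero diagonal. With non-orthogonal patterns the stored
#' patterns interfere, which is what limits the DHNN's storage capacity to
#' roughly 0.13n-0.15n patterns.
#'
#' @param modes list of bipolar patterns (or a matrix, one pattern per row).
#' @param alpha positive gain constant (default 1); pure scaling, recall is
#'   invariant to it.
#' @return an n x n numeric weight matrix.
#' @examples
#' W <- hebbian_weights(list(c(1, 1, -1, 1, 1), c(1, -1, 1, -1, -1)))
#' all(diag(W) == 0)
#' @export
hebbian_weights <- function(modes, alpha = 1) {
  if (is.matrix(modes)) modes <- lapply(seq_len(nrow(modes)), function(i) modes[i, ])
  if (!length(modes)) stop("at least one pattern is required")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a positive number")
  n <- length(modes[[1]])
  W <- matrix(0, n, n)
  for (k in seq_along(modes)) {
    x <- validate_bipolar(modes[[k]], sprintf("modes[[%d]]", k))
    if (length(x) != n)
      stop(sprintf("pattern %d has length %d, expected %d", k, length(x), n))
    W <- W + tcrossprod(x) - diag(n)
  }
  alpha * W
}

#' Bipolar sign activation
#'
#' Component-wise sign with an explicit convention at zero. The default
#' maps exactly-zero pre-activations to -1, which is the convention needed
#' to reproduce single-step recall arithmetic where a zero pre-activation
#' yields an inhibited unit; `"plus"` maps zero to +1, and `"keep"` keeps
#' the unit's previous state (requires `previous`).
#'
#' @param v numeric vector of pre-activations.
#' @param zero one of `"minus"` (default), `"plus"`, `"keep"`.
#' @param previous previous bipolar state, required when `zero = "keep"`.
#' @return a bipolar vector in \{-1, 1\}.
#' @export
sgn_bipolar <- function(v, zero = c("minus", "plus", "keep"), previous = NULL) {
  zero <- match.arg(zero)
  out <- ifelse(v > 0, 1, -1)
  if (zero == "plus") out[v == 0] <- 1
  if (zero == "keep") {
    if (is.null(previous)) stop("`previous` is required when zero = \"keep\"")
    out[v == 0] <- previous[v == 0]
  }
  as.numeric(out)
}

#' One synchronous recall step
#'
#' Applies sgn(W x): the whole state vector is updated at once from the
#' pre-activations.
#'
#' @param W weight matrix from [hebbian_weights()].
#' @param x bipolar state vector.
#' @param zero sign-of-zero convention, see [sgn_bipolar()].
#' @return the next bipolar state.
#' @export
recall_step <- function(W, x, zero = "minus") {
  x <- validate_bipolar(x)
  if (ncol(W) != length(x))
    stop(sprintf("state has length %d, weights are %d x %d",
                 length(x), nrow(W), ncol(W)))
  sgn_bipolar(as.numeric(W %*% x), zero = zero,
              previous = if (zero == "keep") x else NULL)
}

#' Iterated recall to a fixed point
#'
#' Repeats synchronous recall steps until the state stops changing or
#' `max_iter` steps elapse. Synchronous dynamics with symmetric weights can
#' enter 2-cycles, reported as `"cycle_or_cap"`.
#'
#' @param W weight matrix.
#' @param x initial bipolar state.
#' @param max_iter maximum number of steps (default 100).
#' @param zero sign-of-zero convention.
#' @return a list with `state` (final bipolar vector), `outcome` (one of
#'   `"fixed_point"`, `"cycle_or_cap"`), and `iterations` used.
#' @export
dhnn_recall <- function(W, x, max_iter = 100, zero = "minus") {
  if (max_iter < 1) stop("`max_iter` must be at least 1")
  cur <- validate_bipolar(x)
  for (i in seq_len(max_iter)) {
    nxt <- recall_step(W, cur, zero = zero)
    if (identical(nxt, cur))
      return(list(state = cur, outcome = "fixed_point", iterations = i - 1L))
    cur <- nxt
  }
  list(state = cur, outcome = "cycle_or_cap", iterations = max_iter)
}

#' Monte-Carlo storage-capacity experiment
#'
#' For each load m, samples m distinct random bipolar patterns, stores them
#' in both a Hebbian DHNN and an STP memory (with E_c set to the number of
#' corruption flips), probes each stored pattern after flipping `flips`
#' random bits, and reports the fraction of probes recalled exactly.
#'
#' DHNN recall succeeds when one synchronous step returns the original
#' pattern. STP recall succeeds when recognition returns the original
#' pattern's index, either exactly (flips = 0: always, by the fixed-point
#' property) or as the unique most probable candidate of the learned
#' column.
#'
#' @param n pattern length.
#' @param m_values integer vector of pattern counts to test (each <= 2^n).
#' @param trials number of independent replicates per m.
#' @param flips number of corrupted bits per probe (0 <= flips <= n).
#' @param seed integer seed; every trial derives its own sub-seed from it.
#' @return a data.frame with columns `model`, `n`, `m`, `flips`, `trials`,
#'   `recall_fraction`, `seed`.
#' @examples
#' \donttest{
#' capacity_experiment(16, c(2, 6), trials = 5, flips = 0, seed = 1)
#' }
#' @export
capacity_experiment <- function(n, m_values, trials, flips, seed) {
  if (any(m_values > 2^n)) stop("m cannot exceed 2^n")
  if (flips > n) stop("`flips` cannot exceed n")
  rows <- list()
  for (m in m_values) {
    hits <- c(dhnn = 0, stp = 0)
    total <- 0
    for (t in seq_len(trials)) {
      sub <- (seed * 1009 + m * 131 + t) %% .Machine$integer.max
      pats <- generate_patterns(n, m, seed = sub)
      W <- hebbian_weights(pats)
      mem <- stp_memory(pats, bec = flips)
      for (k in seq_along(pats)) {
        probe <- corrupt_mode(pats[[k]], flips, seed = sub + 7 * k)
        total <- total + 1
        if (identical(recall_step(W, probe), pats[[k]]))
          hits["dhnn"] <- hits["dhnn"] + 1
        res <- recognize(mem, probe)
        if (res$status != "rejected") {
          col <- res$distribution
          top <- col$index[col$prob == max(col$prob)]
          if (length(top) == 1L && top == stored_indices(mem)[k])
            hits["stp"] <- hits["stp"] + 1
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = c("dhnn", "stp"), n = n, m = m, flips = flips, trials = trials,
      recall_fraction = as.numeric(hits / total), seed = seed)
  }
  do.call(rbind, rows)
}
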