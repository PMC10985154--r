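#' @title Pattern encodings
#' @description
#' A pattern over n binary neurons has three equivalent representations:
#' the bipolar form X in \{-1, +1\}^n (activation / inhibition), the binary
#' form Y in \{0, 1\}^n, and the canonical-vector (algebraic) form
#' delta_{2^n}^r. Component 1 of the pattern is the most significant bit of
#' the index: the all-ones pattern maps to r = 1 and the all-zeros pattern
#' to r = 2^n. Conversions are strict — components outside the accepted
#' alphabet are rejected, never coerced.
#' @name encoding
NULL

validate_bipolar <- function(x, arg = "x") {
  if (length(x) < 1L) stop(sprintf("`%s` must be a non-empty vector", arg))
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(-1, 1)))
    stop(sprintf("`%s` must have components in {-1, 1}", arg))
  as.numeric(x)
}

validate_binary <- function(y, arg = "y") {
  if (length(y) < 1L) stop(sprintf("`%s` must be a non-empty vector", arg))
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1)))
    stop(sprintf("`%s` must have components in {0, 1}", arg))
  as.numeric(y)
}

#' Convert a bipolar pattern to its binary form
#'
#' Maps each component l_i to k_i = 1 if l_i = 1 and k_i = 0 otherwise.
#'
#' @param x numeric vector with components in \{-1, 1\}.
#' @return numeric vector of the same length with components in \{0, 1\}.
#' @examples
#' bipolar_to_binary(c(1, 1, -1, 1, 1))  # 1 1 0 1 1
#' @export
bipolar_to_binary <- function(x) {
  x <- validate_bipolar(x)
  as.numeric(x == 1)
}

#' Convert a binary pattern to its bipolar form
#'
#' Inverse of [bipolar_to_binary()]: 1 stays 1, 0 becomes -1.
#'
#' @param y numeric vector with components in \{0, 1\}.
#' @return numeric vector with components in \{-1, 1\}.
#' @export
binary_to_bipolar <- function(y) {
  y <- validate_binary(y)
  2 * y - 1
}

#' Index of a binary pattern in the canonical-vector enumeration
#'
#' The binary pattern Y = (k_1, ..., k_n) corresponds to the canonical
#' vector delta_{2^n}^r with
#' \deqn{r = (1-k_1)2^{n-1} + (1-k_2)2^{n-2} + \dots + (1-k_{n-1})2 + (2-k_n).}
#' Indices are exact for n up to 53 (double-precision integer range).
#'
#' @param y numeric vector with components in \{0, 1\}.
#' @return the 1-based index r in `1..2^n`.
#' @examples
#' binary_to_index(c(1, 1, 0, 1, 1))  # 5
#' @export
binary_to_index <- function(y) {
  y <- validate_binary(y)
  n <- length(y)
  if (n > 53) stop("patterns longer than 53 bits exceed exact index range")
  sum((1 - y) * 2^((n - 1):0)) + 1
}

#' Binary pattern corresponding to a canonical-vector index
#'
#' Inverse of [binary_to_index()]: bit j of the pattern is
#' 1 minus the binary digit of r - 1 at weight 2^(n-j).
#'
#' @param r index in `1..2^n`.
#' @param n pattern length.
#' @return numeric vector of length `n` with components in \{0, 1\}.
#' @examples
#' index_to_binary(29, 5)  # 0 0 0 1 1
#' @export
index_to_binary <- function(r, n) {
  if (length(r) != 1L || is.na(r) || r != floor(r) || r < 1 || r > 2^n)
    stop(sprintf("`r` must be an integer in 1..2^%d", n))
  v <- r - 1
  y <- numeric(n)
  for (j in n:1) {
    y[j] <- 1 - (v %% 2)
    v <- v %/% 2
  }
  y
}

#' Encode a bipolar pattern as a canonical vector
#'
#' The algebraic form of a pattern: each component k_i becomes the
#' two-dimensional canonical vector delta_2^(2 - k_i), and the semi-tensor
#' product of the chain collapses to a single canonical vector of dimension
#' 2^n. The closed-form index of [binary_to_index()] gives the same result;
#' both paths are exposed so they can be checked against each other.
#'
#' @param x numeric vector with components in \{-1, 1\}.
#' @param via `"closed_form"` (default) uses the index formula; `"chain"`
#'   folds the STP chain of the per-bit canonical vectors.
#' @return a [canonical_vector()] of dimension 2^n.
#' @examples
#' encode_mode(c(1, -1, 1, -1, -1))  # delta_32^12
#' @export
encode_mode <- function(x, via = c("closed_form", "chain")) {
  via <- match.arg(via)
  y <- bipolar_to_binary(x)
  if (via == "closed_form")
    return(canonical_vector(2^length(y), binary_to_index(y)))
  Reduce(stp_canonical, lapply(y, function(k) canonical_vector(2, 2 - k)))
}

#' Hamming distance between two patterns
#'
#' Number of positions at which the patterns differ. Both patterns must be
#' in the same alphabet (\{0,1\} or \{-1,1\}); the distance is invariant
#' under the bipolar/binary conversion.
#'
#' @param a,b numeric vectors of equal length, both binary or both bipolar.
#' @return a non-negative integer count.
#' @examples
#' hamming_distance(c(0, 1, 0, 1, 1), c(1, 0, 1, 0, 0))  # 5
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("patterns have different lengths")
  if (all(a %in% c(-1, 1))) a <- bipolar_to_binary(a) else a <- validate_binary(a, "a")
  if (all(b %in% c(-1, 1))) b <- bipolar_to_binary(b) else b <- validate_binary(b, "b")
  sum(a != b)
}
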