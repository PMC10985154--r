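#' Canonical basis vector delta_N^i
#'
#' A canonical vector is the i-th column of the N x N identity matrix,
#' written delta_N^i. Patterns of n binary neurons are encoded as canonical
#' vectors of dimension N = 2^n, which is the "algebraic form" used by the
#' semi-tensor product memory model. Only the pair (dim, index) is stored;
#' the dense column is materialized on demand.
#'
#' @param dim positive integer (or exact double), the dimension N.
#' @param index integer in `1..dim` (1-based, as in the delta notation).
#' @return an object of class `canonical_vector` with fields `dim`, `index`.
#' @examples
#' d <- canonical_vector(32, 5)
#' as.matrix(d)[5, 1]  # 1
#' @export
canonical_vector <- function(dim, index) {
  if (length(dim) != 1L || is.na(dim) || dim < 1 || dim != floor(dim))
    stop("`dim` must be a positive integer")
  if (length(index) != 1L || is.na(index) || index < 1 || index > dim ||
      index != floor(index))
    stop("`index` must be an integer in 1..dim")
  structure(list(dim = as.numeric(dim), index = as.numeric(index)),
            class = "canonical_vector")
}

#' @export
print.canonical_vector <- function(x, ...) {
  cat(sprintf("delta_%s^%s\n", format(x$dim, scientific = FALSE),
              format(x$index, scientific = FALSE)))
  invisible(x)
}

#' @export
as.matrix.canonical_vector <- function(x, ...) {
  if (x$dim > 2^20) stop("canonical vector too large to densify")
  m <- matrix(0, nrow = x$dim, ncol = 1L)
  m[x$index, 1L] <- 1
  m
}

#' @export
`==.canonical_vector` <- function(e1, e2) {
  inherits(e1, "canonical_vector") && inherits(e2, "canonical_vector") &&
    e1$dim == e2$dim && e1$index == e2$index
}

#' Kronecker product
#'
#' Thin wrapper around base [kronecker()], kept so the algebra layer exposes
#' the product that the semi-tensor product is built from.
#'
#' @param a,b numeric matrices.
#' @return the Kronecker product `a %x% b`.
#' @export
kron <- function(a, b) {
  kronecker(as.matrix(a), as.matrix(b))
}

#' Semi-tensor product of matrices
#'
#' The semi-tensor product (STP) generalizes the matrix product to arbitrary
#' shapes. For A (m x n) and B (p x q), with r = lcm(n, p),
#' \deqn{A \ltimes B = (A \otimes I_{r/n})(B \otimes I_{r/p}),}
#' a matrix of shape (m r/n) x (q r/p). When n = p the STP reduces to the
#' ordinary matrix product. No shape is ever rejected: the STP is total.
#'
#' @param a,b numeric matrices (vectors are treated as column matrices).
#' @return the STP, a numeric matrix.
#' @examples
#' x <- matrix(c(1, 2, 3), ncol = 1)
#' y <- matrix(c(4, 5), ncol = 1)
#' stp(x, y)  # (4,5,8,10,12,15)^T
#' @export
stp <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  n <- ncol(a)
  p <- nrow(b)
  r <- lcm_int(n, p)
  (a %x% diag(r / n)) %*% (b %x% diag(r / p))
}

lcm_int <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a / g(a, b) * b
}

#' Semi-tensor product of canonical vectors (sparse fast path)
#'
#' For canonical vectors the STP never needs a dense matrix:
#' delta_M^i STP delta_N^j = delta_(MN)^((i-1)N + j). This is the index
#' arithmetic behind the pattern encoding chain; it agrees with densifying,
#' applying [stp()], and re-sparsifying.
#'
#' @param u,v `canonical_vector` objects.
#' @return a `canonical_vector` of dimension `u$dim * v$dim`.
#' @examples
#' stp_canonical(canonical_vector(2, 2), canonical_vector(2, 1))  # delta_4^3
#' @export
stp_canonical <- function(u, v) {
  stopifnot(inherits(u, "canonical_vector"), inherits(v, "canonical_vector"))
  canonical_vector(u$dim * v$dim, (u$index - 1) * v$dim + v$index)
}
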