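# Shared fixtures and independent brute-force oracles.

# The four 5-node learning modes used throughout the worked examples.
ex1_modes <- list(
  c( 1,  1, -1,  1,  1),   # X1 ~ 11011 ~ delta_32^5
  c( 1, -1,  1, -1, -1),   # X2 ~ 10100 ~ delta_32^12
  c(-1,  1,  1, -1,  1),   # X3 ~ 01101 ~ delta_32^19
  c(-1, -1, -1,  1,  1)    # X4 ~ 00011 ~ delta_32^29
)

# Hebbian weight matrix for ex1_modes (alpha = 1), entered row by row.
ex1_W <- matrix(c(
   0,  0,  0,  0, -2,
   0,  0,  0,  0,  2,
   0,  0,  0, -4, -2,
   0,  0, -4,  0,  2,
  -2,  2, -2,  2,  0), nrow = 5, byrow = TRUE)

# Kronecker product by the element-wise index formula
# (kron)_{(i-1)p+k, (j-1)q+l} = a_ij * b_kl — independent of base kronecker().
kron_bruteforce <- function(a, b) {
  p <- nrow(b); q <- ncol(b)
  out <- matrix(0, nrow(a) * p, ncol(a) * q)
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    for (k in seq_len(p)) for (l in seq_len(q))
      out[(i - 1) * p + k, (j - 1) * q + l] <- a[i, j] * b[k, l]
  out
}

# Dense canonical vector without going through the package's constructor.
dense_delta <- function(dim, index) {
  m <- matrix(0, dim, 1)
  m[index, 1] <- 1
  m
}

# Dense algebraic form of a bipolar pattern via the per-bit STP chain on
# dense one-hot columns; independent of the closed-form index arithmetic.
dense_encode_oracle <- function(x) {
  cols <- lapply(x, function(l) dense_delta(2, if (l == 1) 1 else 2))
  Reduce(stp, cols)
}

# Dense memory matrix built from explicit outer products of the dense
# algebraic forms.
dense_L_oracle <- function(modes) {
  n <- length(modes[[1]])
  L <- matrix(0, 2^n, 2^n)
  for (x in modes) {
    d <- dense_encode_oracle(x)
    L <- L + d %*% t(d)
  }
  L
}

# Brute-force column update: inverse-distance weights over stored patterns
# within the BEC window, computed straight from the patterns.
update_oracle <- function(modes, probe, ec) {
  s <- vapply(modes, function(m) sum(bipolar_to_binary(m) != bipolar_to_binary(probe)),
              numeric(1))
  inside <- which(s > 0 & s <= ec)
  if (!length(inside)) return(NULL)
  w <- 1 / s[inside]
  list(k = inside, prob = w / sum(w), s = s[inside])
}
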