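#' Read patterns from a plain-text file
#'
#' Two dialects, one per file (never mixed):
#' * `bitstring` — each line is a string over \{0,1\}; the leftmost
#'   character is component 1 (the most significant bit of the index
#'   formula). `1` maps to +1, `0` to -1.
#' * `signed_tokens` — each line is whitespace-separated `1` / `-1` tokens.
#'
#' Lines starting with `#` and blank lines are ignored. All patterns must
#' share one length; illegal characters are rejected with the offending
#' line number, never coerced.
#'
#' @param path path to the pattern file.
#' @return a list of bipolar patterns with attributes `dialect` and `path`.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop(sprintf("pattern file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no patterns in file")
  dialect <- NULL
  pats <- vector("list", length(keep))
  n <- NULL
  for (j in seq_along(keep)) {
    line <- trimws(raw[keep[j]])
    lineno <- keep[j]
    this <- if (grepl("^[01]+$", line)) "bitstring"
            else if (grepl("^(-?1)(\\s+-?1)*$", line)) "signed_tokens"
            else stop(sprintf("line %d: unrecognized pattern syntax: '%s'", lineno, line))
    if (is.null(dialect)) dialect <- this
    else if (this != dialect)
      stop(sprintf("line %d: dialect '%s' mixed with '%s'", lineno, this, dialect))
    x <- if (this == "bitstring")
      2 * as.numeric(strsplit(line, "")[[1]]) - 1
    else
      as.numeric(strsplit(line, "\\s+")[[1]])
    if (is.null(n)) n <- length(x)
    else if (length(x) != n)
      stop(sprintf("line %d: pattern length %d differs from %d", lineno, length(x), n))
    pats[[j]] <- validate_bipolar(x, sprintf("line %d", lineno))
  }
  attr(pats, "dialect") <- dialect
  attr(pats, "path") <- path
  pats
}

#' Write patterns to a plain-text file
#'
#' @param patterns list of bipolar patterns.
#' @param path output file path.
#' @param dialect `"bitstring"` (default) or `"signed_tokens"`.
#' @return the path, invisibly.
#' @export
write_patterns <- function(patterns, path, dialect = c("bitstring", "signed_tokens")) {
  dialect <- match.arg(dialect)
  lines <- vapply(patterns, function(x) {
    x <- validate_bipolar(x)
    if (dialect == "bitstring") paste(bipolar_to_binary(x), collapse = "")
    else paste(x, collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate random bipolar patterns
#'
#' Samples m distinct patterns uniformly from \{-1,1\}^n, deterministically
#' for a given seed. The caller's RNG state is left untouched.
#'
#' @param n pattern length.
#' @param m number of distinct patterns (m <= 2^n).
#' @param seed integer seed.
#' @return a list of m bipolar patterns.
#' @export
generate_patterns <- function(n, m, seed) {
  if (m > 2^n) stop(sprintf("cannot draw %s distinct patterns of length %d",
                            format(m, scientific = FALSE), n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (n <= 24 && m > 2^n / 2) {
    # dense regime: sample indices without replacement, exact and fast
    idx <- sample.int(2^n, m)
    return(lapply(idx, function(r) binary_to_bipolar(index_to_binary(r, n))))
  }
  seen <- new.env(parent = emptyenv())
  out <- vector("list", m)
  got <- 0L
  while (got < m) {
    x <- sample(c(-1, 1), n, replace = TRUE)
    key <- paste(x, collapse = "")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- x
    }
  }
  out
}

#' Corrupt a pattern by flipping bits
#'
#' Flips exactly `flips` distinct, uniformly chosen positions, so the
#' Hamming distance between input and output is exactly `flips`.
#'
#' @param x bipolar pattern.
#' @param flips number of positions to flip (0 <= flips <= n).
#' @param seed integer seed.
#' @return the corrupted bipolar pattern.
#' @export
corrupt_mode <- function(x, flips, seed) {
  x <- validate_bipolar(x)
  if (flips > length(x)) stop("`flips` cannot exceed the pattern length")
  if (flips == 0) return(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  pos <- sample.int(length(x), flips)
  x[pos] <- -x[pos]
  x
}
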