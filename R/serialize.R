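#' Serialize a memory to JSON
#'
#' Writes `{n, bec, stored, learned}` with 1-based delta indices: `stored`
#' is the index list in insertion order and `learned` maps each learned
#' probe index to its `{stored_index: probability}` support. Round-trip
#' stable via [read_memory_json()].
#'
#' @param mem an `stp_memory`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return the path (invisibly), or the JSON string when `path` is `NULL`.
#' @export
write_memory_json <- function(mem, path = NULL) {
  stopifnot(inherits(mem, "stp_memory"))
  learned <- lapply(mem$cache$learned, function(col) {
    p <- as.list(col$prob)
    names(p) <- format(col$index, scientific = FALSE, trim = TRUE)
    p
  })
  doc <- list(n = mem$n, bec = mem$cache$bec,
              stored = mem$stored,
              learned = if (length(learned)) learned else structure(list(), names = character(0)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Restore a memory from its JSON serialization
#'
#' @param path a file path or a JSON string produced by [write_memory_json()].
#' @return an `stp_memory` with the stored set, E_c, and learned columns
#'   restored.
#' @export
read_memory_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- doc$n
  modes <- lapply(doc$stored, function(r) binary_to_bipolar(index_to_binary(r, n)))
  mem <- stp_memory(modes, bec = doc$bec)
  for (key in names(doc$learned)) {
    entry <- doc$learned[[key]]
    idx <- as.numeric(names(entry))
    prob <- as.numeric(unlist(entry))
    # recover exact rationals from the distances, matching update_column
    update_column(mem, as.numeric(key))
    cached <- mem$cache$learned[[key]]
    if (is.null(cached) || !isTRUE(all.equal(sort(cached$index), sort(idx))))
      mem$cache$learned[[key]] <- prob_column(index = idx, prob = prob,
                                              num = rep(NA_integer_, length(idx)),
                                              den = rep(NA_integer_, length(idx)))
  }
  mem
}

#' Transition edges of a memory
#'
#' One row per nonzero entry of the conceptual matrix L, over all indexes
#' learned so far (or all 2^n when `learn = TRUE`): the probe (source)
#' index, the stored (target) index, and the transition probability.
#' Stored patterns contribute their self-loop with probability 1. This is
#' the edge list of the state transition diagram of L.
#'
#' @param mem an `stp_memory`.
#' @param learn if `TRUE`, first run [learn_all()] so every mode within
#'   E_c of a stored pattern contributes edges.
#' @param cap passed to [learn_all()].
#' @return a data.frame with columns `source`, `target`, `probability`.
#' @export
transition_edges <- function(mem, learn = FALSE, cap = 16) {
  stopifnot(inherits(mem, "stp_memory"))
  if (learn) learn_all(mem, cap = cap)
  src <- c(mem$stored, as.numeric(names(mem$cache$learned)))
  rows <- lapply(src, function(r) {
    col <- memory_column(mem, r)
    data.frame(source = rep(r, length(col$index)), target = col$index,
               probability = col$prob)
  })
  out <- do.call(rbind, c(rows, list(data.frame(source = numeric(0),
                                                target = numeric(0),
                                                probability = numeric(0)))))
  out[order(out$source, out$target), , drop = FALSE]
}

#' Write transition edges as TSV
#' @param mem an `stp_memory`.
#' @param path output file path.
#' @inheritParams transition_edges
#' @return the path, invisibly.
#' @export
write_transitions_tsv <- function(mem, path, learn = FALSE, cap = 16) {
  edges <- transition_edges(mem, learn = learn, cap = cap)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the state transition diagram as a DOT graph
#'
#' Stored patterns are drawn as doubled circles with their probability-1
#' self-loops; learned probes point to their candidate stored patterns
#' with edges labeled by probability.
#'
#' @param mem an `stp_memory`.
#' @param path output file path.
#' @inheritParams transition_edges
#' @return the path, invisibly.
#' @export
write_transitions_dot <- function(mem, path, learn = FALSE, cap = 16) {
  edges <- transition_edges(mem, learn = learn, cap = cap)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c("digraph memory {", "  rankdir=LR;")
  for (r in mem$stored)
    lines <- c(lines, sprintf('  "%s" [shape=doublecircle];', fmt(r)))
  for (i in seq_len(nrow(edges)))
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                              fmt(edges$source[i]), fmt(edges$target[i]),
                              format(edges$probability[i], digits = 12)))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
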