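test_that("stp_memory stores the encoded indices in insertion order", {
  mem <- stp_memory(ex1_modes, bec = 2)
  expect_equal(stored_indices(mem), c(5, 12, 19, 29))
  expect_equal(get_bec(mem), 2)

  expect_error(stp_memory(c(ex1_modes, ex1_modes[1]), bec = 0), "duplicate")
  expect_error(stp_memory(list(c(1, -1), c(1, -1, 1)), bec = 0), "length")

  empty <- stp_memory(list(), bec = 0)
  expect_length(stored_indices(empty), 0)
})

test_that("dense memory matrix equals the brute-force outer-product sum", {
  set.seed(3)
  for (i in 1:5) {
    n <- 3
    modes <- generate_patterns(n, m = 3, seed = 100 + i)
    mem <- stp_memory(modes, bec = 0)
    expect_equal(dense_memory_matrix(mem), dense_L_oracle(modes))
  }
})

test_that("memory columns are point masses on stored indices, zero elsewhere", {
  mem <- stp_memory(ex1_modes, bec = 2)
  col12 <- memory_column(mem, 12)
  expect_equal(col12$index, 12)
  expect_equal(col12$prob, 1)
  expect_true(is_zero_column(memory_column(mem, 21)))
  expect_error(memory_column(mem, 33), "1\\.\\.2")
})

test_that("the BEC update reproduces the inverse-distance column", {
  mem <- stp_memory(ex1_modes, bec = 2)
  col <- update_column(mem, 21)
  expect_equal(col$index, c(5, 19, 29))
  expect_equal(col$prob, c(2, 1, 2) / 5)
  expect_equal(col$num / col$den, c(2, 1, 2) / 5)
  # cached afterwards
  expect_equal(memory_column(mem, 21)$prob, c(0.4, 0.2, 0.4))

  expect_error(update_column(mem, 12), "stored")

  # E_c = 0: the window 0 < s <= 0 is empty, nothing learned or cached
  mem0 <- stp_memory(ex1_modes, bec = 0)
  expect_true(is_zero_column(update_column(mem0, 21)))
  expect_true(is_zero_column(memory_column(mem0, 21)))

  # E_c = n: every stored mode participates; check against the oracle
  memn <- stp_memory(ex1_modes, bec = 5)
  for (r in c(2, 21, 32)) {
    col <- update_column(memn, r)
    o <- update_oracle(ex1_modes, binary_to_bipolar(index_to_binary(r, 5)), 5)
    expect_equal(col$index, stored_indices(memn)[o$k])
    expect_equal(col$prob, o$prob)
  }
})

test_that("recognize walks the recognition/learning procedure", {
  mem <- stp_memory(ex1_modes, bec = 2)

  res <- recognize(mem, c(1, -1, 1, -1, -1))
  expect_equal(res$status, "recognized_exact")
  expect_equal(res$distribution$index, 12)
  expect_equal(res$distribution$prob, 1)

  res <- recognize(mem, c(-1, 1, -1, 1, 1))
  expect_equal(res$status, "classified_by_association")
  expect_equal(res$query_index, 21)
  expect_equal(res$distribution$prob, c(0.4, 0.2, 0.4))

  # a probe strictly farther than E_c = 1 from every stored mode is rejected
  mem1 <- stp_memory(ex1_modes, bec = 1)
  far <- binary_to_bipolar(c(1, 1, 1, 1, 0))
  dmin <- min(vapply(ex1_modes, hamming_distance, numeric(1), b = far))
  expect_gt(dmin, 1)
  expect_equal(recognize(mem1, far)$status, "rejected")
  # rejection is not cached: raising E_c reconsiders the probe
  set_bec(mem1, 2)
  expect_equal(recognize(mem1, far)$status, "classified_by_association")
})

test_that("classify_sample is deterministic and tracks the distribution", {
  mem <- stp_memory(ex1_modes, bec = 2)
  exact <- recognize(mem, ex1_modes[[3]])
  expect_equal(classify_sample(exact, seed = 1), 19)
  expect_equal(classify_sample(exact, seed = 99), 19)

  assoc <- recognize(mem, c(-1, 1, -1, 1, 1))
  expect_equal(classify_sample(assoc, seed = 4), classify_sample(assoc, seed = 4))

  draws <- vapply(1:20000, function(s) classify_sample(assoc, seed = s), numeric(1))
  freq <- as.numeric(table(factor(draws, levels = c(5, 19, 29)))) / length(draws)
  sigma <- sqrt(c(0.4, 0.2, 0.4) * c(0.6, 0.8, 0.6) / length(draws))
  expect_true(all(abs(freq - c(0.4, 0.2, 0.4)) < 3 * sigma))

  rej <- recognize(stp_memory(ex1_modes, bec = 0), c(-1, 1, -1, 1, 1))
  expect_error(classify_sample(rej, seed = 1), "rejected")
})

test_that("learn_all yields the full column map and the rejected count", {
  mem <- stp_memory(ex1_modes, bec = 2)
  cols <- learn_all(mem)
  expect_length(cols, 32)
  expect_equal(cols[[21]]$index, c(5, 19, 29))
  expect_equal(cols[[21]]$prob, c(0.4, 0.2, 0.4))
  for (r in stored_indices(mem)) {
    expect_equal(cols[[r]]$index, r)
    expect_equal(cols[[r]]$prob, 1)
  }
  # rejected columns are exactly the modes farther than E_c from all stored
  n_rejected <- sum(vapply(seq_len(32), function(r) is_zero_column(cols[[r]]), logical(1)))
  far <- sum(vapply(1:32, function(r) {
    x <- binary_to_bipolar(index_to_binary(r, 5))
    min(vapply(ex1_modes, hamming_distance, numeric(1), b = x)) > 2
  }, logical(1)))
  expect_equal(n_rejected, far)

  expect_error(learn_all(stp_memory(list(rep(1, 20)), bec = 1)), "cap")
})

test_that("dense matrix is Boolean diagonal before updates and idempotent", {
  mem <- stp_memory(ex1_modes, bec = 2)
  L <- dense_memory_matrix(mem)
  expect_true(all(L %in% c(0, 1)))
  expect_equal(as.numeric(which(diag(L) == 1)), c(5, 12, 19, 29))
  expect_equal(sum(L), 4)
  expect_equal(sum(diag(L)), 4)
  expect_equal(L %*% L, L)
  expect_equal(dense_memory_matrix(stp_memory(list(), bec = 0)), matrix(0, 1, 1))
})

test_that("learned columns obey the probability laws (random memories)", {
  set.seed(17)
  for (trial in 1:8) {
    n <- 6
    m <- sample(2:6, 1)
    ec <- sample(1:4, 1)
    modes <- generate_patterns(n, m, seed = 500 + trial)
    mem <- stp_memory(modes, bec = ec)
    cols <- learn_all(mem)
    for (r in seq_len(2^n)) {
      col <- cols[[r]]
      if (is_zero_column(col) || r %in% stored_indices(mem)) next
      probe <- index_to_binary(r, n)
      s <- vapply(col$index, function(rk)
        hamming_distance(probe, index_to_binary(rk, n)), numeric(1))
      # sums to one; support within the E_c ball; positivity
      expect_equal(sum(col$prob), 1, tolerance = 1e-12)
      expect_true(all(s >= 1 & s <= ec))
      expect_true(all(col$prob > 0))
      # inverse-distance law: probability x distance constant in a column
      expect_equal(max(col$prob * s) - min(col$prob * s), 0, tolerance = 1e-12)
      # closer stored patterns never get lower probability
      ord <- order(s)
      expect_true(all(diff(col$prob[ord]) <= 1e-12))
    }
  }
})

test_that("sparse columns agree with the dense matrix after updates", {
  set.seed(23)
  for (trial in 1:4) {
    n <- sample(3:6, 1)
    modes <- generate_patterns(n, m = 3, seed = 900 + trial)
    mem <- stp_memory(modes, bec = 2)
    learn_all(mem)
    L <- dense_memory_matrix(mem)
    for (r in seq_len(2^n)) {
      col <- memory_column(mem, r)
      dense_col <- L[, r]
      expect_equal(as.numeric(which(dense_col != 0)), sort(col$index))
      expect_equal(dense_col[col$index], col$prob, ignore_attr = TRUE)
    }
  }
})

test_that("JSON serialization round-trips the memory", {
  mem <- stp_memory(ex1_modes, bec = 2)
  recognize(mem, c(-1, 1, -1, 1, 1))   # learn column 21
  path <- withr::local_tempfile(fileext = ".json")
  write_memory_json(mem, path)
  back <- read_memory_json(path)
  expect_equal(stored_indices(back), stored_indices(mem))
  expect_equal(get_bec(back), 2)
  col <- memory_column(back, 21)
  expect_equal(col$index, c(5, 19, 29))
  expect_equal(col$prob, c(0.4, 0.2, 0.4))
})

test_that("transition edges mirror the learned structure", {
  mem <- stp_memory(ex1_modes, bec = 2)
  edges <- transition_edges(mem, learn = TRUE)
  # every stored pattern has its probability-1 self-loop
  self <- edges[edges$source == edges$target, ]
  expect_equal(sort(self$source), c(5, 12, 19, 29))
  expect_true(all(self$probability == 1))
  e21 <- edges[edges$source == 21, ]
  expect_equal(e21$target, c(5, 19, 29))
  expect_equal(e21$probability, c(0.4, 0.2, 0.4))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_transitions_tsv(mem, tsv)
  write_transitions_dot(mem, dot)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(edges))
  dot_txt <- readLines(dot)
  expect_true(any(grepl("doublecircle", dot_txt)))
  expect_true(any(grepl('"21" -> "5"', dot_txt, fixed = TRUE)))
})

test_that("set_bec invalidates learned columns", {
  mem <- stp_memory(ex1_modes, bec = 2)
  recognize(mem, c(-1, 1, -1, 1, 1))
  expect_false(is_zero_column(memory_column(mem, 21)))
  set_bec(mem, 3)
  expect_true(is_zero_column(memory_column(mem, 21)))
  col <- update_column(mem, 21)
  # at E_c = 3 the same three modes are within reach (distances 1, 2, 1)
  expect_equal(col$index, c(5, 19, 29))
  expect_equal(col$prob, c(0.4, 0.2, 0.4))
})
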