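# Independent oracle: evaluate multi-head attention literally, token pair
# by token pair, with explicit loops over heads, rows and columns.
mha_oracle <- function(M, params) {
  d_k <- params$d_k
  lay <- params$layers[[1L]]
  n <- nrow(M)
  heads <- lapply(lay$heads, function(h) {
    Q <- M %*% h$Wq; K <- M %*% h$Wk; V <- M %*% h$Wv
    H <- matrix(0, n, d_k)
    for (i in seq_len(n)) {
      scores <- vapply(seq_len(n), function(j) {
        sum(Q[i, ] * K[j, ]) / sqrt(d_k)
      }, 1)
      w <- exp(scores - max(scores)); w <- w / sum(w)
      for (j in seq_len(n)) H[i, ] <- H[i, ] + w[j] * V[j, ]
    }
    H
  })
  do.call(cbind, heads) %*% lay$Wo
}

test_that("tokenization wraps the overlapping k-mers with specials", {
  expect_identical(tokenize_kmers("ATCGGGCTA", 3),
                   c("[CLS]", "ATC", "TCG", "CGG", "GGG", "GGC", "GCT",
                     "CTA", "[SEP]"))
  expect_identical(tokenize_kmers("AAA", 3), c("[CLS]", "AAA", "[SEP]"))
  s200 <- random_dataset(1, length = 200)$seq
  expect_length(tokenize_kmers(s200, 3), 200L - 3L + 1L + 2L)
  expect_error(tokenize_kmers("AC", 3), "shorter")
})

test_that("k-mer vocabulary has 4^k + 2 ordered tokens for k in 1..6", {
  for (k in 1:6) {
    tok <- kmer_tokenizer(k)
    expect_length(tok$vocabulary, 4L^k + 2L)
    kmers <- tok$vocabulary[seq_len(4L^k)]
    expect_identical(kmers, sort(kmers))  # lexicographic A<C<G<T
    expect_identical(utils::tail(tok$vocabulary, 2), c("[CLS]", "[SEP]"))
  }
})

test_that("overlapping k-mer tokens reassemble the original sequence", {
  s <- random_dataset(1, length = 37, seed = 12)$seq
  for (k in c(2, 3, 5)) {
    toks <- tokenize_kmers(s, k)
    kmers <- toks[-c(1L, length(toks))]
    rebuilt <- paste0(kmers[1L],
                      paste(substring(kmers[-1L], k, k), collapse = ""))
    expect_identical(rebuilt, s)
  }
})

test_that("multi-head attention matches the per-pair brute-force oracle", {
  enfusion:::with_seed(21, {
    for (rep_i in 1:5) {
      n <- sample(2:10, 1)
      params <- attention_params(n_layers = 1, n_heads = 2, model_dim = 8,
                                 seed = rep_i)
      M <- matrix(stats::rnorm(n * 8), n, 8)
      expect_equal(multi_head_attention(M, params), mha_oracle(M, params),
                   tolerance = 1e-9)
    }
  })
})

test_that("attention weights are row-stochastic and handle edge inputs", {
  params <- attention_params(1, 2, 8, seed = 3)
  M <- matrix(stats::rnorm(48), 6, 8)
  out <- multi_head_attention(M, params, return_weights = TRUE)
  for (A in attr(out, "weights")) {
    expect_equal(unname(rowSums(A)), rep(1, 6), tolerance = 1e-9)
  }

  # single token: softmax over one element is exactly 1
  one <- multi_head_attention(M[1, , drop = FALSE], params,
                              return_weights = TRUE)
  for (A in attr(one, "weights")) expect_equal(A, matrix(1, 1, 1))

  # zero value/output projections give uniform rows and an all-zero output
  z <- params
  for (h in seq_along(z$layers[[1]]$heads)) {
    z$layers[[1]]$heads[[h]]$Wq[] <- 0
    z$layers[[1]]$heads[[h]]$Wk[] <- 0
    z$layers[[1]]$heads[[h]]$Wv[] <- 0
  }
  zo <- multi_head_attention(M, z, return_weights = TRUE)
  expect_true(all(zo == 0))
  for (A in attr(zo, "weights")) {
    expect_equal(A, matrix(1 / 6, 6, 6), tolerance = 1e-12)
  }
  expect_error(multi_head_attention(M[, 1:5], params), "model_dim")
})

test_that("one-hot embedding emits indicator rows of width 4^k", {
  ds <- random_dataset(2, length = 200, seed = 4)
  E <- embed_dataset(ds, onehot_embedder(3))
  expect_length(E, 2L)
  expect_identical(dim(E[[1]]), c(198L, 64L))
  expect_true(all(rowSums(E[[1]]) == 1))
  # the indicator column is the lexicographic index of each k-mer
  toks <- tokenize_kmers(ds$seq[1], 3)
  kmers <- toks[-c(1, length(toks))]
  expect_identical(max.col(E[[1]]), match(kmers, enfusion:::all_kmers(3)))
})

test_that("imported embeddings are validated against L - k + 1 rows", {
  ds <- random_dataset(2, length = 30, seed = 8)
  dir <- withr::local_tempdir()
  M1 <- matrix(stats::rnorm(28 * 5), 28, 5)
  write.table(M1, file.path(dir, paste0(ds$id[1], ".emb.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(matrix(0, 28, 5), file.path(dir, paste0(ds$id[2], ".emb.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  E <- embed_dataset(ds, import_embedder(dir, k = 3))
  expect_equal(E[[1]], M1, tolerance = 1e-12)

  # wrong row count is rejected with the sequence named
  write.table(matrix(0, 27, 5), file.path(dir, paste0(ds$id[2], ".emb.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(embed_dataset(ds, import_embedder(dir, k = 3)), ds$id[2])
})

test_that("masked-span pre-training reduces the loss deterministically", {
  ds <- random_dataset(20, length = 40, seed = 30)
  emb <- train_toy_embedder(ds, k = 3, n_layers = 1, n_heads = 2,
                            model_dim = 16, epochs = 4, lr = 3e-3, seed = 7)
  expect_lt(utils::tail(emb$losses, 1), emb$losses[1])

  emb2 <- train_toy_embedder(ds, k = 3, n_layers = 1, n_heads = 2,
                             model_dim = 16, epochs = 4, lr = 3e-3, seed = 7)
  expect_identical(emb$losses, emb2$losses)

  E <- embed_dataset(ds, emb)
  expect_identical(dim(E[[1]]), c(38L, 16L))  # specials dropped
  expect_true(all(is.finite(E[[1]])))

  expect_error(train_toy_embedder(ds, mask_fraction = 0), "mask_fraction")
  expect_error(train_toy_embedder(ds, mask_fraction = 1), "mask_fraction")
})
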