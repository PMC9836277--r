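# Independent transcription of the five printed LSTM gate equations,
# written with per-gate matrices and explicit order f, s, M', M, o, output.
lstm_oracle <- function(I_t, H_prev, M_prev, cell) {
  z <- c(H_prev, I_t)
  sig <- function(x) 1 / (1 + exp(-x))
  f_t <- sig(drop(cell$Wf %*% z) + cell$bf)
  s_t <- sig(drop(cell$Wi %*% z) + cell$bs)
  Mp  <- tanh(drop(cell$WM %*% z) + cell$bM)
  M_t <- f_t * M_prev + s_t * Mp
  o_t <- sig(drop(cell$Wo %*% z) + cell$bo)
  list(H = o_t * tanh(M_t), M = M_t)
}

rand_cell <- function(u, d, seed) {
  enfusion:::with_seed(seed, {
    mk <- function() matrix(stats::rnorm(u * (u + d)), u, u + d)
    list(Wf = mk(), Wi = mk(), WM = mk(), Wo = mk(),
         bf = stats::rnorm(u), bs = stats::rnorm(u), bM = stats::rnorm(u),
         bo = stats::rnorm(u))
  })
}

test_that("relu follows its piecewise definition", {
  expect_identical(relu(-1), 0)
  expect_identical(relu(2), 2)
  expect_identical(relu(0), 0)
  expect_identical(relu(c(-3, 0.5, 0)), c(0, 0.5, 0))
})

test_that("lstm_step reproduces the closed forms at zero weights", {
  cell <- rand_cell(1, 2, 1)
  for (w in c("Wf", "Wi", "WM", "Wo")) cell[[w]][] <- 0
  for (b in c("bf", "bs", "bM", "bo")) cell[[b]][] <- 0

  r0 <- lstm_step(c(0, 0), 0, 0, cell)
  expect_identical(r0$M, 0)
  expect_identical(r0$H, 0)

  # with M_prev = 1: M_t = sigma(0) * 1 = 0.5, H = 0.5 * tanh(0.5)
  r1 <- lstm_step(c(0, 0), 0, 1, cell)
  expect_equal(r1$M, 0.5)
  expect_equal(r1$H, 0.5 * tanh(0.5), tolerance = 1e-9)
  expect_equal(r1$H, 0.23106, tolerance = 1e-4)
})

test_that("lstm_step matches the independent gate-equation transcription", {
  enfusion:::with_seed(99, {
    for (rep_i in 1:5) {
      u <- sample(1:4, 1); d <- sample(1:5, 1)
      cell <- rand_cell(u, d, rep_i + 10)
      H <- stats::rnorm(u); M <- stats::rnorm(u)
      for (step in 1:3) {
        I_t <- stats::rnorm(d)
        got <- lstm_step(I_t, H, M, cell)
        want <- lstm_oracle(I_t, H, M, cell)
        expect_equal(got$H, want$H, tolerance = 1e-9)
        expect_equal(got$M, want$M, tolerance = 1e-9)
        H <- got$H; M <- got$M
      }
    }
  })
  cell <- rand_cell(2, 3, 1)
  expect_error(lstm_step(c(1, 1), c(0, 0), c(0, 0), cell), "columns")
})

test_that("the batched BiLSTM recursion agrees with repeated lstm_step calls", {
  u <- 3L; d <- 2L; T_ <- 6L
  W <- enfusion:::with_seed(5, matrix(stats::rnorm((u + d) * 4 * u), u + d, 4 * u))
  b <- enfusion:::with_seed(6, stats::rnorm(4 * u))
  X <- enfusion:::with_seed(7, array(stats::rnorm(2 * T_ * d), c(2, T_, d)))
  fwd <- enfusion:::lstm_forward_dir(X, W, b, reverse = FALSE)
  # repack the fused weight matrix into the per-gate cell layout
  cell <- list(Wf = t(W[, 1:u]), Wi = t(W[, u + 1:u]),
               WM = t(W[, 2 * u + 1:u]), Wo = t(W[, 3 * u + 1:u]),
               bf = b[1:u], bs = b[u + 1:u], bM = b[2 * u + 1:u],
               bo = b[3 * u + 1:u])
  for (n in 1:2) {
    H <- numeric(u); M <- numeric(u)
    for (t_i in seq_len(T_)) {
      st <- lstm_step(X[n, t_i, ], H, M, cell)
      H <- st$H; M <- st$M
      expect_equal(unname(fwd$H[n, t_i, ]), unname(H), tolerance = 1e-12)
    }
  }
})

test_that("network gradients match finite differences", {
  ns <- asNamespace("enfusion")
  cfg <- seqnet_config(kernel_widths = c(3, 2), filters = c(3, 2),
                       lstm_units = 2, attention_dim = 2, seed = 5)
  X <- enfusion:::with_seed(42, array(stats::rnorm(3 * 7 * 4), c(3, 7, 4)))
  y <- c(0L, 1L, 1L)
  params <- ns$with_seed(5, ns$init_seqnet_params(4L, cfg))
  fwd <- ns$seqnet_forward(params, X, cache = TRUE)
  grads <- ns$seqnet_backward(params, fwd, y)
  loss_at <- function(p) ns$ce_loss(ns$seqnet_forward(p, X)$prob, y)
  get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }
  set_path <- function(x, path, v) {
    if (length(path) == 1L) { x[[path[[1L]]]] <- v; return(x) }
    x[[path[[1L]]]] <- set_path(x[[path[[1L]]]], path[-1L], v)
    x
  }
  eps <- 1e-6
  paths <- list(list("head", "Wd"), list("att", "Wa"), list("att", "ua"),
                list("lstm", 1L, "W"), list("lstm", 2L, "W"),
                list("conv", 1L, "W", 1L), list("conv", 2L, "W", 2L),
                list("conv", 1L, "b"))
  enfusion:::with_seed(8, {
    for (path in paths) {
      arr <- get_path(params, path)
      for (ii in sample(length(arr), min(3, length(arr)))) {
        a1 <- arr; a1[ii] <- a1[ii] + eps
        a2 <- arr; a2[ii] <- a2[ii] - eps
        num <- (loss_at(set_path(params, path, a1)) -
                loss_at(set_path(params, path, a2))) / (2 * eps)
        expect_lt(abs(get_path(grads, path)[ii] - num),
                  1e-5 * max(1, abs(num)))
      }
    }
  })
})

test_that("training guards, early stopping and loss decrease hold", {
  sim <- motif_dataset(20, 20, length = 40, seed = 77)
  E <- embed_dataset(sim$dataset, onehot_embedder(2))
  y <- sim$dataset$label
  cfg <- seqnet_config(filters = c(6, 4), lstm_units = 3, attention_dim = 3,
                       epochs = 8, patience = 8, batch_size = 16, lr = 1e-2,
                       seed = 9)
  net <- train_seqnet(E, y, cfg)
  expect_lt(utils::tail(net$train_loss, 1), net$train_loss[1])
  expect_true(all(abs(rowSums(enfusion:::seqnet_forward(net$params,
    enfusion:::stack_embeddings(E))$prob) - 1) < 1e-6))

  expect_error(train_seqnet(E, rep(1L, length(y)), cfg), "both classes")
  Ebad <- E; Ebad[[1]] <- Ebad[[1]][-1, ]
  expect_error(train_seqnet(Ebad, y, cfg), "share token count")

  # patience 1 halts as soon as validation loss stops improving, and the
  # restored best epoch precedes the stop
  cfg1 <- seqnet_config(filters = c(4, 3), lstm_units = 2, attention_dim = 2,
                        epochs = 50, patience = 1, batch_size = 16,
                        lr = 0.05, seed = 3)
  net1 <- train_seqnet(E, y, cfg1)
  expect_lt(net1$stopped_epoch, 50L)
  expect_lte(net1$best_epoch, net1$stopped_epoch)
})

test_that("refined features have dimension 2 x lstm units and are deterministic", {
  sim <- motif_dataset(10, 10, length = 30, seed = 13)
  E <- embed_dataset(sim$dataset, onehot_embedder(2))
  cfg <- seqnet_config(filters = c(4, 3), lstm_units = 4, attention_dim = 3,
                       epochs = 2, batch_size = 8, seed = 2)
  net <- train_seqnet(E, sim$dataset$label, cfg)
  r1 <- extract_refined_features(net, E)
  expect_identical(dim(r1), c(20L, 8L))
  expect_identical(r1, extract_refined_features(net, E))
  expect_identical(rownames(r1), sim$dataset$id)
})

test_that("refined features of separable data support a held-out linear probe", {
  sim <- motif_dataset(60, 60, length = 60, seed = 21)
  E <- embed_dataset(sim$dataset, onehot_embedder(3))
  y <- sim$dataset$label
  cfg <- seqnet_config(epochs = 30, patience = 6, batch_size = 32, lr = 1e-2,
                       weight_decay = 5e-3, val_fraction = 0.15, seed = 4)
  net <- train_seqnet(E, y, cfg)
  expect_gt(max(net$val_acc), 0.8)
  r <- extract_refined_features(net, E)
  tr <- enfusion:::with_seed(10, sample(120, 90))
  probe <- stats::glm.fit(cbind(1, r[tr, ]), y[tr],
                          family = stats::binomial())
  pred <- drop(cbind(1, r[-tr, ]) %*% probe$coefficients) > 0
  expect_gt(mean(pred == (y[-tr] == 1)), 0.8)
})

test_that("occlusion scores localize the planted motif and have length L", {
  sim <- motif_dataset(40, 40, length = 50, seed = 31)
  E <- embed_dataset(sim$dataset, onehot_embedder(3))
  cfg <- seqnet_config(epochs = 20, patience = 5, batch_size = 32, lr = 1e-2,
                       weight_decay = 5e-3, seed = 6)
  net <- train_seqnet(E, sim$dataset$label, cfg)

  pos_ids <- sim$truth$id[sim$truth$true_label == 1L][1:12]
  inside <- outside <- c()
  for (id in pos_ids) {
    s <- sim$dataset$seq[sim$dataset$id == id]
    sc <- occlusion_contribution(net, onehot_embedder(3), s)
    expect_length(sc, 50L)
    span <- sim$spans[[id]]
    idx <- unlist(lapply(seq_len(nrow(span)),
                         function(r) span[r, 1]:span[r, 2]))
    inside <- c(inside, sc[idx])
    outside <- c(outside, sc[-idx])
  }
  expect_gt(mean(inside), mean(outside))

  # constant-output model: zero head weights make every score exactly 0
  net0 <- net
  net0$params$head$Wd[] <- 0
  sc0 <- occlusion_contribution(net0, onehot_embedder(3),
                                sim$dataset$seq[1])
  expect_true(all(sc0 == 0))
})
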