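# Deep sequence network over per-token embedding tensors: two 1-D
# convolution layers with ReLU, a bidirectional LSTM, additive attention
# pooling and a softmax head.  Forward and backward passes are written as
# batched matrix operations (samples x tokens x channels arrays), so
# training cost is dominated by BLAS-level matrix products.

#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`: x for x >= 0, 0 for x < 0.
#'
#' @param x Numeric scalar or array.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' One step of the LSTM gate recursion
#'
#' Applies the five gate equations in order on the concatenated vector
#' `[H_prev, I_t]`:
#' forget `f_t = sigmoid(W_f [H, I] + b_f)`,
#' input signal `s_t = sigmoid(W_i [H, I] + b_s)`,
#' candidate cell `M'_t = tanh(W_M [H, I] + b_M)`,
#' cell `M_t = f_t * M_prev + s_t * M'_t`,
#' output gate `o_t = sigmoid(W_o [H, I] + b_o)`,
#' output `H_t = o_t * tanh(M_t)`.
#'
#' @param I_t Input vector (length d).
#' @param H_prev Previous hidden state (length u).
#' @param M_prev Previous memory cell (length u).
#' @param cell List with gate weight matrices `Wf`, `Wi`, `WM`, `Wo`
#'   (each `u x (u + d)`) and bias vectors `bf`, `bs`, `bM`, `bo`.
#' @return List with elements `H` (the step output) and `M` (the new cell).
#' @export
lstm_step <- function(I_t, H_prev, M_prev, cell) {
  z <- c(H_prev, I_t)
  for (w in c("Wf", "Wi", "WM", "Wo")) {
    if (ncol(cell[[w]]) != length(z)) {
      stop_enfusion(w, " has ", ncol(cell[[w]]), " columns but [H, I] has ",
                    length(z), " entries")
    }
  }
  sig <- function(x) 1 / (1 + exp(-x))
  f_t <- sig(as.vector(cell$Wf %*% z) + cell$bf)
  s_t <- sig(as.vector(cell$Wi %*% z) + cell$bs)
  Mc  <- tanh(as.vector(cell$WM %*% z) + cell$bM)
  M_t <- f_t * M_prev + s_t * Mc
  o_t <- sig(as.vector(cell$Wo %*% z) + cell$bo)
  list(H = o_t * tanh(M_t), M = M_t)
}

#' Sequence-network configuration
#'
#' Defaults follow the selected combination kernel widths (3, 3), filters
#' (32, 16) and 16 BiLSTM units; training uses Adam with early stopping on
#' a held-out split and best-weight restore.
#'
#' @param kernel_widths Widths of the two convolution layers.
#' @param filters Filter counts of the two convolution layers.
#' @param lstm_units Units per LSTM direction (refined feature dimension is
#'   `2 * lstm_units`).
#' @param attention_dim Hidden size of the additive attention-pooling layer.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay; regularizes
#'   the network against memorizing individual training fragments.
#' @param val_fraction Fraction of the training set held out for early
#'   stopping.
#' @param seed Seed for initialization, the validation split and shuffling.
#' @return An object of class `seqnet_config`.
#' @export
seqnet_config <- function(kernel_widths = c(3L, 3L), filters = c(32L, 16L),
                          lstm_units = 16L, attention_dim = 16L,
                          epochs = 100L, patience = 5L, batch_size = 32L,
                          lr = 1e-3, weight_decay = 1e-3, val_fraction = 0.1,
                          seed = 1L) {
  cfg <- list(kernel_widths = as.integer(kernel_widths),
              filters = as.integer(filters),
              lstm_units = as.integer(lstm_units),
              attention_dim = as.integer(attention_dim),
              epochs = as.integer(epochs), patience = as.integer(patience),
              batch_size = as.integer(batch_size), lr = lr,
              weight_decay = weight_decay,
              val_fraction = val_fraction, seed = as.integer(seed))
  stopifnot(length(cfg$kernel_widths) == length(cfg$filters),
            all(cfg$kernel_widths >= 1L), all(cfg$filters >= 1L),
            cfg$lstm_units >= 1L, cfg$attention_dim >= 1L,
            cfg$epochs >= 1L, cfg$patience >= 1L, cfg$batch_size >= 1L,
            cfg$lr > 0, cfg$weight_decay >= 0,
            cfg$val_fraction >= 0, cfg$val_fraction < 1)
  structure(cfg, class = "seqnet_config")
}

# ---------------------------------------------------------------------------
# batched layer primitives (X is an N x T x C array throughout)
# ---------------------------------------------------------------------------

slab_mult <- function(X, idx, W) {
  # (N x |idx| x C) slab times (C x F) -> N x |idx| x F
  d <- dim(X)
  Xs <- X[, idx, , drop = FALSE]
  dim(Xs) <- c(d[1L] * length(idx), d[3L])
  out <- Xs %*% W
  dim(out) <- c(d[1L], length(idx), ncol(W))
  out
}

conv1d_forward <- function(X, W, b) {
  # W: list of width matrices (C x F); same padding, stride 1
  d <- dim(X)
  w <- length(W)
  padL <- (w - 1L) %/% 2L
  Z <- array(rep(b, each = d[1L] * d[2L]), c(d[1L], d[2L], length(b)))
  for (dt in seq_len(w)) {
    off <- dt - 1L - padL
    tv <- max(1L, 1L - off):min(d[2L], d[2L] - off)
    Z[, tv, ] <- Z[, tv, , drop = FALSE] + slab_mult(X, tv + off, W[[dt]])
  }
  Z
}

conv1d_backward <- function(X, W, dZ) {
  d <- dim(X)
  w <- length(W)
  padL <- (w - 1L) %/% 2L
  dX <- array(0, d)
  dW <- vector("list", w)
  for (dt in seq_len(w)) {
    off <- dt - 1L - padL
    tv <- max(1L, 1L - off):min(d[2L], d[2L] - off)
    Xs <- X[, tv + off, , drop = FALSE]
    dim(Xs) <- c(d[1L] * length(tv), d[3L])
    dZs <- dZ[, tv, , drop = FALSE]
    dim(dZs) <- c(d[1L] * length(tv), dim(dZ)[3L])
    dW[[dt]] <- crossprod(Xs, dZs)
    dX[, tv + off, ] <- dX[, tv + off, , drop = FALSE] +
      slab_mult(dZ, tv, t(W[[dt]]))
  }
  db <- colSums(dZ, dims = 2L)
  list(dX = dX, dW = dW, db = db)
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_forward_dir <- function(X, W, b, reverse = FALSE) {
  # X: N x T x D; W: (u + D) x 4u with gate column blocks [f, s, cand, o]
  d <- dim(X)
  u <- ncol(W) %/% 4L
  ts <- if (reverse) rev(seq_len(d[2L])) else seq_len(d[2L])
  H <- matrix(0, d[1L], u)
  C <- matrix(0, d[1L], u)
  Hout <- array(0, c(d[1L], d[2L], u))
  cache <- vector("list", d[2L])
  for (step in seq_along(ts)) {
    t_i <- ts[step]
    Zt <- cbind(H, matrix(X[, t_i, ], d[1L], d[3L]))
    G <- Zt %*% W
    G <- sweep(G, 2L, b, "+")
    f <- sigm(G[, 1:u, drop = FALSE])
    s <- sigm(G[, (u + 1):(2 * u), drop = FALSE])
    cc <- tanh(G[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm(G[, (3 * u + 1):(4 * u), drop = FALSE])
    C_prev <- C
    C <- f * C + s * cc
    tC <- tanh(C)
    H <- o * tC
    Hout[, t_i, ] <- H
    cache[[step]] <- list(Zt = Zt, f = f, s = s, cc = cc, o = o,
                          C = C, C_prev = C_prev, tC = tC)
  }
  list(H = Hout, cache = cache, ts = ts, u = u)
}

lstm_backward_dir <- function(fwd, W, dHout) {
  u <- fwd$u
  d <- dim(dHout)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dX <- array(0, c(d[1L], d[2L], nrow(W) - u))
  dH_next <- matrix(0, d[1L], u)
  dC_next <- matrix(0, d[1L], u)
  for (step in rev(seq_along(fwd$ts))) {
    t_i <- fwd$ts[step]
    ca <- fwd$cache[[step]]
    dH <- matrix(dHout[, t_i, ], d[1L], u) + dH_next
    dC <- dC_next + dH * ca$o * (1 - ca$tC^2)
    dG <- cbind((dC * ca$C_prev) * ca$f * (1 - ca$f),
                (dC * ca$cc) * ca$s * (1 - ca$s),
                (dC * ca$s) * (1 - ca$cc^2),
                (dH * ca$tC) * ca$o * (1 - ca$o))
    dW <- dW + crossprod(ca$Zt, dG)
    db <- db + colSums(dG)
    dZt <- dG %*% t(W)
    dH_next <- dZt[, 1:u, drop = FALSE]
    dX[, t_i, ] <- dZt[, (u + 1):ncol(dZt), drop = FALSE]
    dC_next <- dC * ca$f
  }
  list(dW = dW, db = db, dX = dX)
}

attention_pool_forward <- function(O, Wa, ba, ua) {
  # O: N x T x 2u; additive attention with a learned context vector
  d <- dim(O)
  Of <- O
  dim(Of) <- c(d[1L] * d[2L], d[3L])
  E <- tanh(sweep(Of %*% Wa, 2L, ba, "+"))
  sc <- matrix(E %*% ua, d[1L], d[2L])
  alpha <- row_softmax(sc)
  r <- matrix(0, d[1L], d[3L])
  for (t_i in seq_len(d[2L])) {
    r <- r + alpha[, t_i] * matrix(O[, t_i, ], d[1L], d[3L])
  }
  list(r = r, alpha = alpha, E = E, Of = Of)
}

attention_pool_backward <- function(fwd, O, Wa, ba, ua, dr) {
  d <- dim(O)
  dalpha <- matrix(0, d[1L], d[2L])
  dO <- array(0, d)
  for (t_i in seq_len(d[2L])) {
    Ot <- matrix(O[, t_i, ], d[1L], d[3L])
    dalpha[, t_i] <- rowSums(dr * Ot)
    dO[, t_i, ] <- fwd$alpha[, t_i] * dr
  }
  dsc <- (dalpha - rowSums(dalpha * fwd$alpha)) * fwd$alpha
  dsc_f <- as.vector(dsc)
  dua <- colSums(fwd$E * dsc_f)
  dE <- outer(dsc_f, ua)
  dpre <- dE * (1 - fwd$E^2)
  dWa <- crossprod(fwd$Of, dpre)
  dba <- colSums(dpre)
  dOf <- dpre %*% t(Wa)
  dim(dOf) <- d
  list(dO = dO + dOf, dWa = dWa, dba = dba, dua = dua)
}

init_seqnet_params <- function(D, config) {
  widths <- config$kernel_widths
  filters <- config$filters
  u <- config$lstm_units
  a <- config$attention_dim
  glorot <- function(nin, nout, nr, nc) {
    matrix(stats::runif(nr * nc, -sqrt(6 / (nin + nout)),
                        sqrt(6 / (nin + nout))), nr, nc)
  }
  params <- list(conv = list(), lstm = list(), att = list(), head = list())
  Cin <- D
  for (l in seq_along(widths)) {
    w <- widths[l]; f <- filters[l]
    params$conv[[l]] <- list(
      W = lapply(seq_len(w), function(i) glorot(Cin * w, f, Cin, f)),
      b = numeric(f)
    )
    Cin <- f
  }
  for (dir in 1:2) {
    W <- glorot(Cin + u, 4 * u, Cin + u, 4 * u)
    b <- numeric(4 * u)
    b[1:u] <- 1  # forget-gate bias starts open
    params$lstm[[dir]] <- list(W = W, b = b)
  }
  params$att <- list(Wa = glorot(2 * u, a, 2 * u, a), ba = numeric(a),
                     ua = stats::runif(a, -sqrt(6 / (a + 1)), sqrt(6 / (a + 1))))
  params$head <- list(Wd = glorot(2 * u, 2, 2 * u, 2), bd = numeric(2))
  params
}

seqnet_forward <- function(params, X, cache = FALSE) {
  convs <- list()
  A <- X
  for (l in seq_along(params$conv)) {
    Z <- conv1d_forward(A, params$conv[[l]]$W, params$conv[[l]]$b)
    R <- pmax(Z, 0)
    convs[[l]] <- list(input = A, Z = Z)
    A <- R
  }
  fw <- lstm_forward_dir(A, params$lstm[[1L]]$W, params$lstm[[1L]]$b, FALSE)
  bw <- lstm_forward_dir(A, params$lstm[[2L]]$W, params$lstm[[2L]]$b, TRUE)
  d <- dim(fw$H)
  O <- array(0, c(d[1L], d[2L], 2L * d[3L]))
  O[, , seq_len(d[3L])] <- fw$H
  O[, , d[3L] + seq_len(d[3L])] <- bw$H
  ap <- attention_pool_forward(O, params$att$Wa, params$att$ba, params$att$ua)
  logits <- sweep(ap$r %*% params$head$Wd, 2L, params$head$bd, "+")
  prob <- row_softmax(logits)
  out <- list(prob = prob, r = ap$r, alpha = ap$alpha)
  if (cache) {
    out$cache <- list(convs = convs, conv_out = A, fw = fw, bw = bw, O = O,
                      ap = ap, logits = logits)
  }
  out
}

seqnet_backward <- function(params, fwd, y) {
  ca <- fwd$cache
  N <- nrow(fwd$prob)
  dlog <- fwd$prob
  dlog[cbind(seq_len(N), y + 1L)] <- dlog[cbind(seq_len(N), y + 1L)] - 1
  dlog <- dlog / N
  g <- list(conv = list(), lstm = list(), att = list(), head = list())
  g$head$Wd <- crossprod(ca$ap$r, dlog)
  g$head$bd <- colSums(dlog)
  dr <- dlog %*% t(params$head$Wd)
  ab <- attention_pool_backward(ca$ap, ca$O, params$att$Wa, params$att$ba,
                                params$att$ua, dr)
  g$att <- list(Wa = ab$dWa, ba = ab$dba, ua = ab$dua)
  u <- dim(ca$fw$H)[3L]
  dHf <- ab$dO[, , seq_len(u), drop = FALSE]
  dHb <- ab$dO[, , u + seq_len(u), drop = FALSE]
  bf <- lstm_backward_dir(ca$fw, params$lstm[[1L]]$W, dHf)
  bb <- lstm_backward_dir(ca$bw, params$lstm[[2L]]$W, dHb)
  g$lstm[[1L]] <- list(W = bf$dW, b = bf$db)
  g$lstm[[2L]] <- list(W = bb$dW, b = bb$db)
  dA <- bf$dX + bb$dX
  for (l in rev(seq_along(params$conv))) {
    dZ <- dA * (ca$convs[[l]]$Z > 0)
    cb <- conv1d_backward(ca$convs[[l]]$input, params$conv[[l]]$W, dZ)
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  g
}

ce_loss <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12)))
}

stack_embeddings <- function(embeddings) {
  dims <- vapply(embeddings, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop_enfusion("all embedding tensors must share token count and dimension")
  }
  X <- array(0, c(length(embeddings), dims[1L, 1L], dims[2L, 1L]))
  for (i in seq_along(embeddings)) X[i, , ] <- embeddings[[i]]
  X
}

#' Train the convolutional BiLSTM sequence network
#'
#' Trains conv(ReLU) -> conv(ReLU) -> BiLSTM -> additive attention pooling
#' -> softmax on per-sequence embedding tensors, using Adam with minibatch
#' gradient descent, a stratified held-out split for early stopping, and
#' best-weight restore.  Training is deterministic under a fixed seed.
#'
#' @param embeddings List of per-sequence embedding matrices, all of shape
#'   `(tokens x dim)` (see [embed_dataset()]).
#' @param labels Binary 0/1 vector, one per sequence; both classes must be
#'   present.
#' @param config A [seqnet_config()].
#' @return An object of class `enfusion_seqnet` with the fitted parameters,
#'   per-epoch `train_loss`/`val_loss`/`val_acc` histories, and the epoch
#'   whose weights were restored (`best_epoch`).
#' @export
train_seqnet <- function(embeddings, labels, config = seqnet_config()) {
  stopifnot(inherits(config, "seqnet_config"))
  y <- as.integer(labels)
  if (length(embeddings) != length(y)) {
    stop_enfusion("labels must be parallel to embeddings")
  }
  if (length(unique(y)) < 2L) {
    stop_enfusion("both classes must be present to train the network")
  }
  X <- stack_embeddings(embeddings)
  N <- dim(X)[1L]; D <- dim(X)[3L]

  with_seed(derive_seed(config$seed, "seqnet"), {
    # stratified validation split
    n_val <- max(2L, round(config$val_fraction * N))
    val_idx <- c()
    for (cl in c(0L, 1L)) {
      ids <- which(y == cl)
      take <- max(1L, round(n_val * length(ids) / N))
      val_idx <- c(val_idx, sample(ids, min(take, length(ids) - 1L)))
    }
    tr_idx <- setdiff(seq_len(N), val_idx)

    params <- init_seqnet_params(D, config)
    opt <- adam_state(params)
    Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , , drop = FALSE]; yval <- y[val_idx]

    train_loss <- val_loss <- val_acc <- numeric(0)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(ytr))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        fwd <- seqnet_forward(params, Xtr[bi, , , drop = FALSE], cache = TRUE)
        ep_loss <- ep_loss + ce_loss(fwd$prob, ytr[bi]) * length(bi)
        grads <- seqnet_backward(params, fwd, ytr[bi])
        st <- adam_step(params, grads, opt, lr = config$lr,
                        weight_decay = config$weight_decay)
        params <- st$params; opt <- st$state
      }
      train_loss[ep] <- ep_loss / length(ytr)
      vfwd <- seqnet_forward(params, Xval)
      val_loss[ep] <- ce_loss(vfwd$prob, yval)
      val_acc[ep] <- mean((vfwd$prob[, 2L] > 0.5) == (yval == 1L))
      if (val_loss[ep] < best$loss - 1e-6) {
        best <- list(loss = val_loss[ep], params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(
      params = best$params, config = config, input_dim = D,
      n_tokens = dim(X)[2L], refined_dim = 2L * config$lstm_units,
      train_loss = train_loss, val_loss = val_loss, val_acc = val_acc,
      best_epoch = best$epoch, stopped_epoch = length(train_loss)
    ), class = "enfusion_seqnet")
  })
}

#' @export
print.enfusion_seqnet <- function(x, ...) {
  cat("<enfusion_seqnet> input ", x$n_tokens, " x ", x$input_dim,
      ", refined dim ", x$refined_dim, ", best epoch ", x$best_epoch,
      "/", x$stopped_epoch, "\n", sep = "")
  invisible(x)
}

#' Positive-class probabilities from the sequence network
#'
#' @param model An `enfusion_seqnet`.
#' @param embeddings List of embedding matrices, same shape as at training.
#' @return Numeric vector of enhancer probabilities.
#' @export
predict_seqnet <- function(model, embeddings) {
  stopifnot(inherits(model, "enfusion_seqnet"))
  X <- stack_embeddings(embeddings)
  seqnet_forward(model$params, X)$prob[, 2L]
}

#' Extract refined dynamic features
#'
#' Returns the attention-pooled BiLSTM representation, one row per
#' sequence, of dimension `2 * lstm_units` (32 with defaults).
#'
#' @param model An `enfusion_seqnet`.
#' @param embeddings List of embedding matrices (optionally named by
#'   sequence id).
#' @return Numeric matrix `length(embeddings) x refined_dim`.
#' @export
extract_refined_features <- function(model, embeddings) {
  stopifnot(inherits(model, "enfusion_seqnet"))
  if (is.null(model$params)) stop_enfusion("model is not fitted")
  X <- stack_embeddings(embeddings)
  r <- seqnet_forward(model$params, X)$r
  dimnames(r) <- list(names(embeddings),
                      paste0("dyn_", seq_len(ncol(r))))
  r
}

#' Per-base occlusion contribution scores
#'
#' Scores position p as the model's positive-class probability on the
#' original sequence minus the mean probability over the three sequences
#' with position p substituted by each alternative base.  High scores mark
#' bases whose identity the model relies on (e.g. planted motif positions).
#'
#' @param model A fitted `enfusion_seqnet`.
#' @param embedder The `enfusion_embedder` used to embed training data.
#' @param seq A single A/C/G/T sequence string.
#' @return Numeric score vector of length `nchar(seq)`.
#' @export
occlusion_contribution <- function(model, embedder, seq) {
  stopifnot(inherits(model, "enfusion_seqnet"),
            inherits(embedder, "enfusion_embedder"))
  seq <- validate_seq_arg(seq)
  L <- nchar(seq)
  variants <- character(3L * L)
  v <- 0L
  for (p in seq_len(L)) {
    ref <- substr(seq, p, p)
    for (alt in setdiff(DNA_BASES, ref)) {
      v <- v + 1L
      s2 <- seq
      substr(s2, p, p) <- alt
      variants[v] <- s2
    }
  }
  all_seqs <- seq_dataset(paste0("v", 0:(3L * L)), c(seq, variants))
  emb <- embed_dataset(all_seqs, embedder)
  probs <- predict_seqnet(model, emb)
  p0 <- probs[1L]
  alt <- matrix(probs[-1L], nrow = 3L)
  p0 - colMeans(alt)
}
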