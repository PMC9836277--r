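# Dynamic semantic embedding: k-mer tokenization, multi-head self-attention,
# a desk-scale transformer encoder trained with a masked-span objective, a
# one-hot fallback backend, and an import path for externally precomputed
# embedding matrices.

CLS_TOKEN <- "[CLS]"
SEP_TOKEN <- "[SEP]"
MASK_TOKEN <- "[MASK]"  # internal training symbol, not part of the vocabulary

#' Build the k-mer tokenizer vocabulary
#'
#' The vocabulary holds all `4^k` k-mers in lexicographic order followed by
#' the sequence-start (`[CLS]`) and sequence-end (`[SEP]`) specials, for
#' `4^k + 2` tokens in total.
#'
#' @param k k-mer size (>= 1).
#' @return An object of class `kmer_tokenizer` with fields `k`,
#'   `vocabulary`, `token_to_index`.
#' @export
kmer_tokenizer <- function(k = 3L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 8L)
  vocabulary <- c(all_kmers(k), CLS_TOKEN, SEP_TOKEN)
  structure(list(
    k = k,
    vocabulary = vocabulary,
    token_to_index = stats::setNames(seq_along(vocabulary), vocabulary)
  ), class = "kmer_tokenizer")
}

#' Tokenize a sequence into overlapping k-mers with specials
#'
#' Emits the sequence-start special, the `L - k + 1` overlapping k-mers in
#' order, then the sequence-end special.
#'
#' @param seq A single A/C/G/T sequence string with `nchar(seq) >= k`.
#' @param k k-mer size.
#' @return Character vector of tokens.
#' @export
tokenize_kmers <- function(seq, k = 3L) {
  seq <- validate_seq_arg(seq)
  k <- as.integer(k)
  if (nchar(seq) < k) {
    stop_enfusion("sequence length ", nchar(seq), " is shorter than k = ", k)
  }
  n <- nchar(seq) - k + 1L
  c(CLS_TOKEN, substring(seq, seq_len(n), seq_len(n) + k - 1L), SEP_TOKEN)
}

# token indices (1-based into the lexicographic k-mer list), without specials
token_indices <- function(seq, k) {
  kmer_codes(base_codes(seq), k) + 1L
}

#' Random multi-head attention parameters
#'
#' Creates `n_layers` transformer encoder layers.  Each layer holds, per
#' head, query/key/value projections `W^Q`, `W^K`, `W^V` of shape
#' `model_dim x d_k` (with `d_k = model_dim / n_heads`), a shared output
#' projection `W^O`, and a small position-wise feed-forward block.
#'
#' @param n_layers Number of encoder layers T.
#' @param n_heads Number of attention heads n (must divide `model_dim`).
#' @param model_dim Embedding/model dimension d.
#' @param seed Seed for the random initialization.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(n_layers = 2L, n_heads = 4L, model_dim = 32L,
                             seed = 1L) {
  n_layers <- as.integer(n_layers); n_heads <- as.integer(n_heads)
  model_dim <- as.integer(model_dim)
  stopifnot(n_layers >= 1L, n_heads >= 1L, model_dim >= n_heads)
  if (model_dim %% n_heads != 0L) {
    stop_enfusion("model_dim (", model_dim, ") must be divisible by n_heads (",
                  n_heads, ")")
  }
  d_k <- model_dim %/% n_heads
  hid <- 2L * model_dim
  sd0 <- 1 / sqrt(model_dim)
  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      heads <- lapply(seq_len(n_heads), function(h) {
        list(Wq = matrix(stats::rnorm(model_dim * d_k, sd = sd0), model_dim, d_k),
             Wk = matrix(stats::rnorm(model_dim * d_k, sd = sd0), model_dim, d_k),
             Wv = matrix(stats::rnorm(model_dim * d_k, sd = sd0), model_dim, d_k))
      })
      list(heads = heads,
           Wo = matrix(stats::rnorm(model_dim * model_dim, sd = sd0),
                       model_dim, model_dim),
           W1 = matrix(stats::rnorm(model_dim * hid, sd = sd0), model_dim, hid),
           b1 = numeric(hid),
           W2 = matrix(stats::rnorm(hid * model_dim, sd = sd0), hid, model_dim),
           b2 = numeric(model_dim))
    })
  })
  structure(list(n_layers = n_layers, n_heads = n_heads,
                 model_dim = model_dim, d_k = d_k, layers = layers,
                 seed = as.integer(seed)),
            class = "attention_params")
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Multi-head scaled dot-product self-attention
#'
#' For each head i: `Q = M W_i^Q`, `K = M W_i^K`, `V = M W_i^V`, attention
#' weights = row-softmax of `Q K^T / sqrt(d_k)`, head output = weights `V`.
#' Heads are concatenated and projected by `W^O`; the output has the shape
#' of the input.
#'
#' @param M Token-by-dimension numeric matrix (`ncol(M) == model_dim`).
#' @param params An [attention_params()] object.
#' @param layer Which layer's weights to apply (default 1).
#' @param return_weights If `TRUE`, attach the per-head attention weight
#'   matrices as attribute `"weights"`.
#' @return Matrix of the same shape as `M`.
#' @export
multi_head_attention <- function(M, params, layer = 1L,
                                 return_weights = FALSE) {
  stopifnot(inherits(params, "attention_params"))
  M <- as.matrix(M)
  if (ncol(M) != params$model_dim) {
    stop_enfusion("input has ", ncol(M), " columns but model_dim is ",
                  params$model_dim)
  }
  lay <- params$layers[[layer]]
  heads <- lapply(lay$heads, function(h) {
    Q <- M %*% h$Wq
    K <- M %*% h$Wk
    V <- M %*% h$Wv
    A <- row_softmax(Q %*% t(K) / sqrt(params$d_k))
    list(H = A %*% V, A = A)
  })
  out <- do.call(cbind, lapply(heads, `[[`, "H")) %*% lay$Wo
  if (return_weights) attr(out, "weights") <- lapply(heads, `[[`, "A")
  out
}

# ---------------------------------------------------------------------------
# Desk-scale transformer embedder (masked-span objective, manual backprop)
# ---------------------------------------------------------------------------

# forward pass through the encoder for integer token indices (already
# including CLS/SEP and possibly MASK); returns hidden states and, when
# cache = TRUE, the intermediates needed for backpropagation
encoder_forward <- function(par, idx, cache = FALSE) {
  n <- length(idx)
  X <- par$E[idx, , drop = FALSE] + par$P[seq_len(n), , drop = FALSE]
  caches <- if (cache) vector("list", length(par$layers))
  for (l in seq_along(par$layers)) {
    lay <- par$layers[[l]]
    inX <- X
    hs <- lapply(lay$heads, function(h) {
      Q <- inX %*% h$Wq
      K <- inX %*% h$Wk
      V <- inX %*% h$Wv
      A <- row_softmax(Q %*% t(K) / par$scale2)
      list(Q = Q, K = K, V = V, A = A, H = A %*% V)
    })
    C <- do.call(cbind, lapply(hs, `[[`, "H"))
    X1 <- inX + C %*% lay$Wo
    Z <- sweep(X1 %*% lay$W1, 2L, lay$b1, "+")
    R <- pmax(Z, 0)
    X <- X1 + sweep(R %*% lay$W2, 2L, lay$b2, "+")
    if (cache) caches[[l]] <- list(inX = inX, hs = hs, C = C, X1 = X1,
                                   Z = Z, R = R)
  }
  list(H = X, caches = caches)
}

# gradient of the encoder given dH at the output; returns gradient list
# mirroring par$layers plus dX0 (gradient at the embedded input)
encoder_backward <- function(par, fwd, dH) {
  gl <- vector("list", length(par$layers))
  dX <- dH
  for (l in rev(seq_along(par$layers))) {
    lay <- par$layers[[l]]
    ca <- fwd$caches[[l]]
    # feed-forward block with residual
    dF <- dX
    dW2 <- crossprod(ca$R, dF)
    db2 <- colSums(dF)
    dR <- dF %*% t(lay$W2)
    dZ <- dR * (ca$Z > 0)
    dW1 <- crossprod(ca$X1, dZ)
    db1 <- colSums(dZ)
    dX1 <- dX + dZ %*% t(lay$W1)
    # attention block with residual
    dO <- dX1
    dWo <- crossprod(ca$C, dO)
    dC <- dO %*% t(lay$Wo)
    dInX <- dX1
    dheads <- vector("list", length(lay$heads))
    for (h in seq_along(lay$heads)) {
      hw <- lay$heads[[h]]
      hc <- ca$hs[[h]]
      cols <- ((h - 1L) * par$d_k + 1L):(h * par$d_k)
      dHh <- dC[, cols, drop = FALSE]
      dA <- dHh %*% t(hc$V)
      dV <- crossprod(hc$A, dHh)
      dS <- (dA - rowSums(dA * hc$A)) * hc$A / par$scale2
      dQ <- dS %*% hc$K
      dK <- crossprod(dS, hc$Q)
      dheads[[h]] <- list(Wq = crossprod(ca$inX, dQ),
                          Wk = crossprod(ca$inX, dK),
                          Wv = crossprod(ca$inX, dV))
      dInX <- dInX + dQ %*% t(hw$Wq) + dK %*% t(hw$Wk) + dV %*% t(hw$Wv)
    }
    gl[[l]] <- list(heads = dheads, Wo = dWo, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2)
    dX <- dInX
  }
  list(layers = gl, dX0 = dX)
}

# Adam over arbitrarily nested lists of numeric arrays.  Parameters,
# gradients and both moment accumulators share one nesting structure, so a
# single recursion updates everything in place.
nested_zero <- function(x) {
  if (is.list(x)) lapply(x, nested_zero) else x * 0
}

adam_state <- function(params) {
  list(m = nested_zero(params), v = nested_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

#' Train the desk-scale transformer embedder
#'
#' Fits a small transformer encoder (learned token + positional embeddings,
#' `n_layers` blocks of multi-head self-attention with residual connection
#' and a position-wise ReLU feed-forward sub-block) with a masked-span
#' objective: contiguous spans of `k` tokens are replaced by an internal
#' mask symbol and the model is trained with cross-entropy to recover the
#' original k-mer indices at the masked positions.  A span of k tokens is
#' masked jointly so that no masked nucleotide survives in an overlapping
#' neighbour token.
#'
#' @param dataset A non-empty [seq_dataset()]; all sequences must have
#'   length >= k.
#' @param k k-mer size (default 3).
#' @param n_layers,n_heads,model_dim Encoder size (defaults 2, 4, 32).
#' @param mask_fraction Fraction of k-mer tokens masked per sequence, in
#'   (0, 1); default 0.15.
#' @param epochs Training epochs (default 5).
#' @param lr Adam learning rate.
#' @param seed Seed controlling initialization and masking; fixed seed
#'   gives bitwise-identical training.
#' @return An object of class `enfusion_embedder` (backend
#'   `"transformer"`) with fields `dim`, `k`, `losses` (per-epoch mean
#'   masked cross-entropy) among others.
#' @export
train_toy_embedder <- function(dataset, k = 3L, n_layers = 2L, n_heads = 4L,
                               model_dim = 32L, mask_fraction = 0.15,
                               epochs = 5L, lr = 1e-3, seed = 1L) {
  stopifnot(inherits(dataset, "seq_dataset"))
  if (length(dataset) == 0L) stop_enfusion("dataset is empty")
  if (!is.numeric(mask_fraction) || mask_fraction <= 0 || mask_fraction >= 1) {
    stop_enfusion("mask_fraction must be strictly inside (0, 1)")
  }
  k <- as.integer(k)
  if (any(nchar(dataset$seq) < k)) {
    stop_enfusion("all sequences must have length >= k = ", k)
  }
  tok <- kmer_tokenizer(k)
  n_kmers <- 4L^k
  cls_i <- n_kmers + 1L; sep_i <- n_kmers + 2L; mask_i <- n_kmers + 3L
  max_len <- max(nchar(dataset$seq)) - k + 3L  # tokens incl. CLS/SEP
  ap <- attention_params(n_layers, n_heads, model_dim,
                         seed = derive_seed(seed, "attn"))
  par <- list(
    E = NULL, P = NULL, layers = ap$layers,
    Wout = NULL, bout = numeric(n_kmers),
    d_k = ap$d_k, scale2 = sqrt(ap$d_k)
  )
  losses <- numeric(epochs)
  par <- with_seed(derive_seed(seed, "embed-init"), {
    sd0 <- 1 / sqrt(model_dim)
    par$E <- matrix(stats::rnorm((n_kmers + 3L) * model_dim, sd = sd0),
                    n_kmers + 3L, model_dim)
    par$P <- matrix(stats::rnorm(max_len * model_dim, sd = sd0),
                    max_len, model_dim)
    par$Wout <- matrix(stats::rnorm(model_dim * n_kmers, sd = sd0),
                       model_dim, n_kmers)
    par
  })
  trainable <- par[c("E", "P", "layers", "Wout", "bout")]
  opt <- adam_state(trainable)

  seq_tokens <- lapply(dataset$seq, function(s) {
    c(cls_i, token_indices(s, k), sep_i)
  })

  with_seed(derive_seed(seed, "embed-train"), {
    for (ep in seq_len(as.integer(epochs))) {
      tot_loss <- 0; tot_pos <- 0L
      for (si in seq_along(seq_tokens)) {
        idx0 <- seq_tokens[[si]]
        n_tok <- length(idx0) - 2L          # maskable k-mer tokens
        n_span <- max(1L, round(mask_fraction * n_tok / k))
        starts <- sample.int(max(1L, n_tok - k + 1L), n_span, replace = TRUE)
        mask_pos <- unique(unlist(lapply(starts, function(s0) {
          s0:min(n_tok, s0 + k - 1L)
        }))) + 1L                           # +1: skip CLS row
        targets <- idx0[mask_pos]
        idx <- idx0
        idx[mask_pos] <- mask_i

        par[names(trainable)] <- trainable
        fwd <- encoder_forward(par, idx, cache = TRUE)
        Hm <- fwd$H[mask_pos, , drop = FALSE]
        logits <- sweep(Hm %*% par$Wout, 2L, par$bout, "+")
        Pm <- row_softmax(logits)
        npos <- length(mask_pos)
        ll <- -sum(log(pmax(Pm[cbind(seq_len(npos), targets)], 1e-12)))
        tot_loss <- tot_loss + ll
        tot_pos <- tot_pos + npos

        dlog <- Pm
        dlog[cbind(seq_len(npos), targets)] <-
          dlog[cbind(seq_len(npos), targets)] - 1
        dlog <- dlog / npos
        gWout <- crossprod(Hm, dlog)
        gbout <- colSums(dlog)
        dH <- matrix(0, length(idx), ncol(fwd$H))
        dH[mask_pos, ] <- dlog %*% t(par$Wout)
        bk <- encoder_backward(par, fwd, dH)
        gE <- par$E * 0
        dX0 <- bk$dX0
        for (r in seq_along(idx)) gE[idx[r], ] <- gE[idx[r], ] + dX0[r, ]
        gP <- par$P * 0
        gP[seq_along(idx), ] <- dX0

        grads <- list(E = gE, P = gP, layers = bk$layers,
                      Wout = gWout, bout = gbout)
        st <- adam_step(trainable, grads, opt, lr = lr)
        trainable <- st$params; opt <- st$state
      }
      losses[ep] <- tot_loss / tot_pos
    }
  })
  par[names(trainable)] <- trainable

  structure(list(
    backend = "transformer", k = k, dim = as.integer(model_dim),
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    mask_fraction = mask_fraction, epochs = as.integer(epochs),
    seed = as.integer(seed), max_len = max_len,
    tokenizer = tok, par = par, losses = losses
  ), class = "enfusion_embedder")
}

#' One-hot embedding backend
#'
#' Represents each k-mer token as a `4^k` indicator row; no training, no
#' special-token rows.
#'
#' @param k k-mer size.
#' @return An `enfusion_embedder` with backend `"onehot"`.
#' @export
onehot_embedder <- function(k = 3L) {
  k <- as.integer(k)
  structure(list(backend = "onehot", k = k, dim = 4L^k,
                 tokenizer = kmer_tokenizer(k)),
            class = "enfusion_embedder")
}

#' Import backend for externally precomputed embeddings
#'
#' Reads per-token embedding matrices produced elsewhere (e.g. by a
#' full-scale pre-trained sequence language model).  Two layouts are
#' supported: a directory of per-sequence files `<id>.emb.tsv` (rows =
#' tokens, columns = dimensions, no header), or a single TSV whose first
#' column `id` indexes rows by sequence.  Each matrix must have exactly
#' `L - k + 1` rows for its sequence.
#'
#' @param path Directory or container file path.
#' @param k k-mer size the embeddings were computed with.
#' @return An `enfusion_embedder` with backend `"import"`.
#' @export
import_embedder <- function(path, k = 3L) {
  if (!file.exists(path)) stop_enfusion("embedding path not found: ", path)
  structure(list(backend = "import", k = as.integer(k), dim = NA_integer_,
                 path = path, tokenizer = kmer_tokenizer(as.integer(k))),
            class = "enfusion_embedder")
}

#' @export
print.enfusion_embedder <- function(x, ...) {
  cat("<enfusion_embedder> backend=", x$backend, ", k=", x$k,
      if (!is.na(x$dim %||% NA)) paste0(", dim=", x$dim), "\n", sep = "")
  invisible(x)
}

#' Embed a dataset into per-sequence token matrices
#'
#' For the transformer backend, runs the encoder and extracts the
#' last-layer hidden states, dropping the rows of the start/end special
#' tokens; the result for a length-L sequence is an `(L - k + 1) x dim`
#' matrix.  The one-hot backend emits `(L - k + 1) x 4^k` indicator rows.
#' The import backend loads and shape-validates external matrices.
#'
#' @param dataset A [seq_dataset()].
#' @param embedder An `enfusion_embedder`.
#' @return Named list of per-sequence embedding matrices.
#' @export
embed_dataset <- function(dataset, embedder) {
  stopifnot(inherits(dataset, "seq_dataset"),
            inherits(embedder, "enfusion_embedder"))
  k <- embedder$k
  if (any(nchar(dataset$seq) < k)) {
    stop_enfusion("all sequences must have length >= k = ", k)
  }
  out <- switch(
    embedder$backend,
    onehot = lapply(dataset$seq, function(s) {
      idx <- token_indices(s, k)
      M <- matrix(0, length(idx), 4L^k)
      M[cbind(seq_along(idx), idx)] <- 1
      M
    }),
    transformer = {
      n_kmers <- 4L^k
      lapply(dataset$seq, function(s) {
        idx <- c(n_kmers + 1L, token_indices(s, k), n_kmers + 2L)
        if (length(idx) > embedder$max_len) {
          stop_enfusion("sequence longer than the embedder's trained ",
                        "positional range (", embedder$max_len, " tokens)")
        }
        H <- encoder_forward(embedder$par, idx)$H
        H[-c(1L, nrow(H)), , drop = FALSE]
      })
    },
    import = load_imported_embeddings(dataset, embedder),
    stop_enfusion("unknown embedder backend: ", embedder$backend)
  )
  names(out) <- dataset$id
  out
}

load_imported_embeddings <- function(dataset, embedder) {
  k <- embedder$k
  if (dir.exists(embedder$path)) {
    mats <- lapply(seq_along(dataset$id), function(i) {
      fp <- file.path(embedder$path, paste0(dataset$id[i], ".emb.tsv"))
      if (!file.exists(fp)) {
        stop_enfusion("no embedding file for sequence '", dataset$id[i], "'")
      }
      as.matrix(utils::read.table(fp, sep = "\t", header = FALSE))
    })
  } else {
    tab <- utils::read.table(embedder$path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    if (colnames(tab)[1L] != "id") {
      stop_enfusion("container embedding file must have first column 'id'")
    }
    mats <- lapply(dataset$id, function(id) {
      rows <- tab$id == id
      if (!any(rows)) stop_enfusion("no embedding rows for sequence '", id, "'")
      as.matrix(tab[rows, -1L, drop = FALSE])
    })
  }
  for (i in seq_along(mats)) {
    expected <- nchar(dataset$seq[i]) - k + 1L
    if (nrow(mats[[i]]) != expected) {
      stop_enfusion("imported matrix for sequence '", dataset$id[i], "' has ",
                    nrow(mats[[i]]), " rows; expected L - k + 1 = ", expected)
    }
    dimnames(mats[[i]]) <- NULL
    storage.mode(mats[[i]]) <- "double"
  }
  mats
}
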