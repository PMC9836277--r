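# Internal helpers shared across modules.

#' @useDynLib enfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic code in the package funnels through this helper so
# results are reproducible from a single integer seed.  Mersenne-Twister with
# Inversion is named explicitly: it is identical across platforms and R
# versions >= 3.6.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Derive a child seed from a master seed and a stage label, keeping the
# result inside the 32-bit signed integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# Integer codes 0..3 (A,C,G,T) for one sequence string; assumes validated.
base_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
}

# All k-mers over ACGT in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  stopifnot(k >= 1)
  grids <- rev(rep(list(DNA_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

# Codes (0-based, lexicographic) of all overlapping k-mers of a coded
# sequence; returns integer(0) when the sequence is shorter than k.
kmer_codes <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(integer(0))
  out <- integer(n)
  for (j in seq_len(k)) {
    out <- out * 4L + codes[j:(j + n - 1L)]
  }
  out
}

stop_enfusion <- function(..., class = "enfusion_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
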