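# Multi-source biological feature encoders: positional gapped k-m-tuple
# pair counts (PGKM), pseudo k-tuple nucleotide composition (PseKNC) and
# the nucleotide physicochemical property block (NPCP).

#' Configuration for the positional gapped k-m-tuple pair encoder
#'
#' A PGKM feature is indexed by a first k-tuple, an exact gap g in
#' 1..`gap_max`, and a second m-tuple; its value is the number of positions
#' in the sequence where that (tuple, gap, tuple) arrangement occurs.  Each
#' (k, m) pair contributes `4^k * 4^m * gap_max` features.
#'
#' @param gap_max Maximum gap n >= 1; every exact gap 1..n is encoded.
#' @param tuple_pairs List of ordered integer pairs `c(k, m)`.  The default
#'   grid is all pairs in \{1,2,3\} x \{1,2,3\} except (3,3), which together
#'   with `gap_max = 5` yields 14,800 features (and 14,891 once the PseKNC
#'   and NPCP blocks are appended).
#' @return An object of class `pgkm_config`.
#' @export
pgkm_config <- function(gap_max = 5L,
                        tuple_pairs = NULL) {
  gap_max <- as.integer(gap_max)
  stopifnot(length(gap_max) == 1L, gap_max >= 1L)
  if (is.null(tuple_pairs)) {
    tuple_pairs <- list(
      c(1L, 1L), c(1L, 2L), c(1L, 3L),
      c(2L, 1L), c(2L, 2L), c(2L, 3L),
      c(3L, 1L), c(3L, 2L)
    )
  }
  tuple_pairs <- lapply(tuple_pairs, function(p) {
    p <- as.integer(p)
    stopifnot(length(p) == 2L, all(p >= 1L), all(p <= 8L))
    p
  })
  key <- vapply(tuple_pairs, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop_enfusion("tuple_pairs must be unique")
  structure(list(gap_max = gap_max, tuple_pairs = tuple_pairs),
            class = "pgkm_config")
}

#' Feature names of a PGKM configuration
#'
#' Names encode the arrangement as `<k-tuple><g underscores><m-tuple>`
#' (e.g. `A_C` for A, gap 1, C; `A___T` for A, gap 3, T).  Ordering is
#' pair-major in configuration order, then gap ascending, then first tuple
#' lexicographic (A < C < G < T), then second tuple lexicographic.
#'
#' @param config A [pgkm_config()].
#' @return Character vector of feature names.
#' @export
pgkm_feature_names <- function(config = pgkm_config()) {
  stopifnot(inherits(config, "pgkm_config"))
  blocks <- lapply(config$tuple_pairs, function(p) {
    a <- all_kmers(p[1L])
    b <- all_kmers(p[2L])
    unlist(lapply(seq_len(config$gap_max), function(g) {
      gap <- strrep("_", g)
      as.vector(t(outer(a, b, function(x, y) paste0(x, gap, y))))
    }))
  })
  unlist(blocks)
}

#' Encode one sequence as PGKM counts
#'
#' Counts, for every configured (k-tuple, exact gap, m-tuple) arrangement,
#' the number of sequence positions i with the k-tuple at i and the m-tuple
#' exactly `gap` bases downstream of it.  Counts are raw integers (not
#' length-normalized); arrangements whose span k + gap + m exceeds the
#' sequence length are 0.
#'
#' @param seq A single A/C/G/T sequence string.
#' @param config A [pgkm_config()].
#' @return Named numeric count vector aligned to [pgkm_feature_names()].
#' @export
encode_pgkm <- function(seq, config = pgkm_config()) {
  stopifnot(inherits(config, "pgkm_config"))
  seq <- validate_seq_arg(seq)
  codes <- base_codes(seq)
  out <- lapply(config$tuple_pairs, function(p) {
    k <- p[1L]; m <- p[2L]
    ck <- kmer_codes(codes, k)   # 0-based codes of k-tuples at each start
    cm <- kmer_codes(codes, m)
    nbin <- 4L^(k + m)
    unlist(lapply(seq_len(config$gap_max), function(g) {
      # first tuple starts at i, second at i + k + g (1-based offsets)
      n_pairs <- length(codes) - k - m - g + 1L
      if (n_pairs < 1L) return(numeric(nbin))
      a <- ck[seq_len(n_pairs)]
      b <- cm[seq_len(n_pairs) + k + g]
      tabulate(a * 4L^m + b + 1L, nbins = nbin)
    }))
  })
  stats::setNames(as.numeric(unlist(out)), pgkm_feature_names(config))
}

#' Configuration for pseudo k-tuple nucleotide composition
#'
#' @param k_max Largest tuple order (default 3); capped at 8 to guard
#'   against exponential feature counts.
#' @return An object of class `pseknc_config`.
#' @export
pseknc_config <- function(k_max = 3L) {
  k_max <- as.integer(k_max)
  stopifnot(length(k_max) == 1L, k_max >= 1L, k_max <= 8L)
  structure(list(k_max = k_max), class = "pseknc_config")
}

#' Feature names of the PseKNC block
#'
#' @param config A [pseknc_config()].
#' @return Character vector, `knc<i>_<tuple>` for i = 1..k_max, tuples in
#'   lexicographic order.
#' @export
pseknc_feature_names <- function(config = pseknc_config()) {
  stopifnot(inherits(config, "pseknc_config"))
  unlist(lapply(seq_len(config$k_max), function(i) {
    paste0("knc", i, "_", all_kmers(i))
  }))
}

#' Encode one sequence as pseudo k-tuple nucleotide composition
#'
#' Concatenates the tuple-frequency vectors V_1..V_k: within V_i the entry
#' for tuple t is its count divided by the number of windows L - i + 1, so
#' each block sums to 1.
#'
#' @param seq A single A/C/G/T sequence string, length >= `k_max`.
#' @param config A [pseknc_config()].
#' @return Named numeric frequency vector of length `sum(4^(1:k_max))`.
#' @export
encode_pseknc <- function(seq, config = pseknc_config()) {
  stopifnot(inherits(config, "pseknc_config"))
  seq <- validate_seq_arg(seq)
  codes <- base_codes(seq)
  if (length(codes) < config$k_max) {
    stop_enfusion("sequence shorter than k_max = ", config$k_max)
  }
  out <- unlist(lapply(seq_len(config$k_max), function(i) {
    ci <- kmer_codes(codes, i)
    tabulate(ci + 1L, nbins = 4L^i) / length(ci)
  }))
  stats::setNames(out, pseknc_feature_names(config))
}

#' Feature names of the physicochemical property block
#'
#' @return Character vector of the 7 NPCP feature names.
#' @export
npcp_feature_names <- function() {
  c("npcp_z_x", "npcp_z_y", "npcp_z_z", "npcp_gc_content",
    "npcp_at_gc_ratio", "npcp_gc_skew", "npcp_at_skew")
}

#' Encode one sequence as nucleotide physicochemical properties
#'
#' Four property families give a 7-dimensional vector (3 + 1 + 1 + 2):
#' \itemize{
#'   \item Z-curve end-point disparities, normalized by length L:
#'     purine/pyrimidine `z_x = ((A+G)-(C+T))/L`, amino/keto
#'     `z_y = ((A+C)-(G+T))/L`, weak/strong `z_z = ((A+T)-(G+C))/L`;
#'   \item GC content `(G+C)/L`;
#'   \item `(A+T)/(C+G)` ratio, capped at L when C+G = 0;
#'   \item GC skew `(G-C)/(G+C)` and AT skew `(A-T)/(A+T)`, each 0 when its
#'     denominator is 0.
#' }
#'
#' @param seq A single non-empty A/C/G/T sequence string.
#' @return Named numeric vector of length 7.
#' @export
encode_npcp <- function(seq) {
  seq <- validate_seq_arg(seq)
  codes <- base_codes(seq)
  L <- length(codes)
  n <- tabulate(codes + 1L, nbins = 4L)  # A, C, G, T
  A <- n[1L]; C <- n[2L]; G <- n[3L]; T_ <- n[4L]
  ratio <- if (C + G == 0) L else (A + T_) / (C + G)
  gc_skew <- if (G + C == 0) 0 else (G - C) / (G + C)
  at_skew <- if (A + T_ == 0) 0 else (A - T_) / (A + T_)
  stats::setNames(
    c(((A + G) - (C + T_)) / L,
      ((A + C) - (G + T_)) / L,
      ((A + T_) - (G + C)) / L,
      (G + C) / L,
      ratio,
      gc_skew,
      at_skew),
    npcp_feature_names()
  )
}

#' Encode a dataset into the fused multi-source feature matrix
#'
#' Column order is the PGKM block, then the PseKNC block, then the NPCP
#' block; feature names are stable across calls with equal configuration.
#' With the default configuration a 200 bp dataset yields 14,891 columns
#' (14,800 + 84 + 7).
#'
#' @param dataset A [seq_dataset()].
#' @param pgkm A [pgkm_config()].
#' @param pseknc A [pseknc_config()].
#' @param use_npcp Include the 7-column physicochemical block?
#' @return Numeric matrix, one row per sequence (rownames = ids, colnames =
#'   feature names).
#' @export
encode_multisource <- function(dataset,
                               pgkm = pgkm_config(),
                               pseknc = pseknc_config(),
                               use_npcp = TRUE) {
  stopifnot(inherits(dataset, "seq_dataset"))
  if (length(dataset) == 0L) stop_enfusion("empty dataset")
  cn <- c(pgkm_feature_names(pgkm), pseknc_feature_names(pseknc),
          if (use_npcp) npcp_feature_names())
  X <- matrix(0, nrow = length(dataset), ncol = length(cn),
              dimnames = list(dataset$id, cn))
  for (i in seq_along(dataset$id)) {
    row <- tryCatch(
      c(encode_pgkm(dataset$seq[i], pgkm),
        encode_pseknc(dataset$seq[i], pseknc),
        if (use_npcp) encode_npcp(dataset$seq[i])),
      error = function(e) {
        stop_enfusion("encoding failed for sample '", dataset$id[i], "': ",
                      conditionMessage(e))
      }
    )
    X[i, ] <- row
  }
  X
}

# Accept either a plain string or a 1-sequence dataset slice; validate.
validate_seq_arg <- function(seq) {
  if (inherits(seq, "seq_dataset")) {
    stopifnot(length(seq) == 1L)
    return(seq$seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop_enfusion("empty sequence")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop_enfusion("invalid character '", substr(seq, bad, bad),
                  "' at position ", bad)
  }
  seq
}
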