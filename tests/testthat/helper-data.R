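# Shared fixture builders; everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dataset <- function(n, length = 60L, seed = 1L, labelled = TRUE) {
  seqs <- enfusion:::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  labels <- if (labelled) rep_len(c(1L, 0L), n) else NULL
  seq_dataset(sprintf("s%03d", seq_len(n)), seqs, labels)
}

write_temp_fasta <- function(dataset, width = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(seq_along(dataset$id), function(i) {
    s <- dataset$seq[i]
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    c(paste0(">", dataset$id[i]), body)
  }))
  writeLines(lines, path)
  path
}

# tiny pipeline configuration so end-to-end tests run in seconds
tiny_pipeline_config <- function(...) {
  pipeline_config(
    pgkm = list(gap_max = 2L, tuple_pairs = list(c(1L, 1L), c(2L, 1L))),
    pseknc = list(k_max = 2L),
    selector = list(n_estimators = 10L, max_depth = 1L),
    embedder = list(backend = "onehot", k = 2L),
    seqnet = list(filters = c(4L, 4L), lstm_units = 3L, attention_dim = 3L,
                  epochs = 2L, patience = 2L, batch_size = 16L),
    ensemble = list(cascade_forest = list(n_forests = 2L, n_trees = 10L,
                                          max_layers = 1L)),
    ...
  )
}

# small separable planted-motif data for learning tests
motif_dataset <- function(n_pos = 30L, n_neg = 30L, length = 60L, seed = 5L) {
  generate_dataset(synthetic_config(
    n_pos = n_pos, n_neg = n_neg, length = length,
    motifs = list(pwm_from_consensus("TGACGTCA", 0.95)), seed = seed
  ))
}
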