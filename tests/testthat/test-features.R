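# Brute-force oracle: count (k-tuple, exact gap, m-tuple) occurrences by an
# exhaustive double loop over start positions, independent of the encoder.
pgkm_oracle <- function(seq, config) {
  names <- pgkm_feature_names(config)
  out <- stats::setNames(numeric(length(names)), names)
  L <- nchar(seq)
  for (p in config$tuple_pairs) {
    k <- p[1]; m <- p[2]
    for (g in seq_len(config$gap_max)) {
      for (i in seq_len(L)) {
        j <- i + k + g  # start of the second tuple
        if (j + m - 1 > L) next
        nm <- paste0(substr(seq, i, i + k - 1), strrep("_", g),
                     substr(seq, j, j + m - 1))
        out[nm] <- out[nm] + 1
      }
    }
  }
  out
}

test_that("PGKM reproduces the worked example for ACCGTA", {
  cfg <- pgkm_config(gap_max = 3, tuple_pairs = list(c(1, 1)))
  nms <- pgkm_feature_names(cfg)
  expect_length(nms, 48L)
  expect_identical(nms[1:4], c("A_A", "A_C", "A_G", "A_T"))
  expect_identical(nms[17], "A__A")  # gap-2 block follows the 16 gap-1 pairs

  v <- encode_pgkm("ACCGTA", cfg)
  nonzero <- c("A_C", "C_G", "C_T", "G_A", "A__G", "C__T", "C__A",
               "A___T", "C___A")
  expect_identical(sort(names(v[v > 0])), sort(nonzero))
  expect_true(all(v[nonzero] == 1))
  expect_identical(unname(sum(v)), 9)
})

test_that("PGKM name registry sizes follow 4^k * 4^m * gap_max", {
  expect_length(pgkm_feature_names(pgkm_config(1, list(c(1, 1)))), 16L)
  expect_length(pgkm_feature_names(pgkm_config()), 14800L)
  # derived: sum over the default 8 tuple pairs of 5 * 4^k * 4^m
  pairs <- pgkm_config()$tuple_pairs
  expect_identical(sum(vapply(pairs, function(p) 5 * 4^p[1] * 4^p[2], 1)),
                   14800)
  expect_error(pgkm_config(3, list(c(1, 1), c(1, 1))), "unique")
})

test_that("PGKM spans beyond the sequence give zero counts", {
  cfg <- pgkm_config(3, list(c(1, 1)))
  expect_true(all(encode_pgkm("AA", cfg) == 0))  # min span 3 > 2
  v <- encode_pgkm("AAAA", pgkm_config(1, list(c(1, 1))))
  expect_identical(unname(v[["A_A"]]), 2)
  expect_identical(unname(sum(v)), 2)
})

test_that("PGKM equals the exhaustive enumeration oracle on random sequences", {
  cfg <- pgkm_config(3, list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
  enfusion:::with_seed(42, {
    for (rep_i in 1:200) {
      L <- sample(1:50, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      expect_identical(encode_pgkm(s, cfg), pgkm_oracle(s, cfg))
    }
  })
})

test_that("PGKM conservation: counts at exact gap g sum to max(0, L-k-m-g+1)", {
  cfg <- pgkm_config(4, list(c(1, 1), c(2, 1), c(2, 3)))
  enfusion:::with_seed(7, {
    for (rep_i in 1:20) {
      L <- sample(2:40, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      v <- encode_pgkm(s, cfg)
      for (p in cfg$tuple_pairs) {
        for (g in seq_len(cfg$gap_max)) {
          pat <- paste0("^[ACGT]{", p[1], "}", strrep("_", g),
                        "[ACGT]{", p[2], "}$")
          expect_equal(unname(sum(v[grepl(pat, names(v))])),
                       max(0, L - p[1] - p[2] - g + 1))
        }
      }
    }
  })
})

test_that("PseKNC concatenates normalized tuple-frequency blocks", {
  v <- encode_pseknc("AAAA", pseknc_config(3))
  expect_length(v, 84L)
  expect_identical(unname(v[c("knc1_A", "knc2_AA", "knc3_AAA")]), c(1, 1, 1))
  expect_identical(unname(sum(v > 0)), 3L)

  expect_identical(unname(encode_pseknc("ACGT", pseknc_config(1))),
                   rep(0.25, 4))
  expect_error(encode_pseknc("AC", pseknc_config(3)), "shorter")

  # each block sums to 1 and matches direct substring counting
  s <- random_dataset(1, length = 200, seed = 9)$seq
  v <- encode_pseknc(s, pseknc_config(3))
  for (i in 1:3) {
    block <- v[startsWith(names(v), paste0("knc", i, "_"))]
    expect_equal(unname(sum(block)), 1, tolerance = 1e-9)
    kmers <- substring(s, 1:(200 - i + 1), i:200)
    tab <- table(kmers)
    expect_equal(unname(block[paste0("knc", i, "_", names(tab))]),
                 as.numeric(tab) / (200 - i + 1))
  }
})

test_that("NPCP evaluates the physicochemical formulas with guards", {
  v <- encode_npcp("ACGT")
  expect_equal(unname(v), c(0, 0, 0, 0.5, 1, 0, 0))

  v <- encode_npcp("ATAT")  # no G/C: ratio capped at L, skew guards at 0
  expect_equal(unname(v[c("npcp_gc_content", "npcp_at_gc_ratio",
                          "npcp_gc_skew", "npcp_at_skew")]), c(0, 4, 0, 0))

  v <- encode_npcp("GGCC")
  expect_equal(unname(v), c(0, 0, -1, 1, 0, 0, 0))
  expect_error(encode_npcp(""), "empty")
})

test_that("multi-source encoding stacks blocks with stable names and order", {
  ds <- random_dataset(6, length = 40, seed = 3)
  X <- encode_multisource(ds, pgkm_config(3, list(c(1, 1))),
                          pseknc_config(1), use_npcp = TRUE)
  expect_identical(dim(X), c(6L, 48L + 4L + 7L))
  expect_identical(rownames(X), ds$id)
  # block order: PGKM, PseKNC, NPCP
  expect_identical(colnames(X)[49], "knc1_A")
  expect_identical(colnames(X)[53], "npcp_z_x")

  # row permutation permutes the matrix rows identically
  perm <- c(4, 1, 6, 2, 3, 5)
  Xp <- encode_multisource(ds[perm], pgkm_config(3, list(c(1, 1))),
                           pseknc_config(1), use_npcp = TRUE)
  expect_identical(Xp, X[perm, ])

  expect_error(encode_multisource(ds[0]), "empty")
  short <- seq_dataset("tiny", "AC")
  expect_error(encode_multisource(short, pgkm_config(3, list(c(1, 1))),
                                  pseknc_config(3)), "tiny")
})
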