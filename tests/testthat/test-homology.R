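test_that("global alignment is exact on forced cases and degaps cleanly", {
  aln <- global_align("ANKYRIN", "ANKYRIN")
  expect_equal(aln$aligned_a, "ANKYRIN")
  expect_equal(aln$aligned_b, "ANKYRIN")
  expect_equal(block_partition(aln)$percent_identity, 100)

  for (st_id in default_aligner_settings()$id) {
    aln2 <- global_align("ACDE", "ACE", st_id)
    expect_equal(gsub("-", "", aln2$aligned_a), "ACDE")
    expect_equal(gsub("-", "", aln2$aligned_b), "ACE")
    expect_equal(nchar(aln2$aligned_a), nchar(aln2$aligned_b))
    ## exactly one gap column, no double-gap columns
    ca <- strsplit(aln2$aligned_a, "")[[1]]
    cb <- strsplit(aln2$aligned_b, "")[[1]]
    expect_equal(sum(cb == "-"), 1L)
    expect_false(any(ca == "-" & cb == "-"))
  }
  expect_error(global_align("AC1E", "ACE"), "non-residue")
})

test_that("alignment scores equal the reference dynamic-programming oracle", {
  set.seed(71)
  grid <- default_aligner_settings()
  for (k in seq_len(nrow(grid))) {
    st <- grid[k, ]
    e <- new.env()
    utils::data(list = st$matrix, package = "Biostrings", envir = e)
    submat <- get(st$matrix, envir = e)
    for (rep in 1:3) {
      a <- random_protein(sample(30:60, 1))
      b <- random_protein(sample(30:60, 1))
      mine <- global_align(a, b, st)
      ref <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = submat, gapOpening = st$gap_open,
        gapExtension = st$gap_extend, type = "global")
      expect_equal(mine$score, Biostrings::score(ref),
                   info = paste(st$id, rep))
    }
  }
})

test_that("block partitioning matches a run-length-encoding oracle", {
  ## one run of 40 identities
  s <- random_protein(40, seed = 4)
  bp <- block_partition(make_alignment(s, s))
  expect_equal(bp$percent_identity, 100)
  expect_equal(bp$block4_pct, 100)
  expect_equal(bp$singlet_pct, 0)

  ## alternating match/mismatch: all singlets
  a <- strrep("AC", 20)
  b <- strrep("AD", 20)
  bp2 <- block_partition(make_alignment(a, b))
  expect_equal(bp2$singlet_pct, 100)
  expect_equal(bp2$block4_pct, 0)

  ## random alignment strings vs the RLE oracle, including gaps
  set.seed(9)
  for (i in 1:5) {
    n <- 80
    ca <- sample(c(AA20[1:4], "-"), n, replace = TRUE,
                 prob = c(rep(0.225, 4), 0.1))
    cb <- sample(c(AA20[1:4], "-"), n, replace = TRUE,
                 prob = c(rep(0.225, 4), 0.1))
    cb[ca == "-" & cb == "-"] <- "A"
    aln <- make_alignment(paste(ca, collapse = ""), paste(cb, collapse = ""))
    bp3 <- block_partition(aln)
    runs <- oracle_run_histogram(aln$aligned_a, aln$aligned_b)
    expect_equal(bp3$n_identities, sum(runs))
    if (sum(runs) > 0) {
      expect_equal(as.integer(bp3$run_length_histogram),
                   as.integer(table(factor(runs, levels = seq_len(max(runs))))))
      ## totals conserved: histogram x run length = identities
      expect_equal(sum(as.integer(bp3$run_length_histogram) *
                         seq_len(max(runs))), bp3$n_identities)
      ## singlets + mid runs + blocks partition the identities
      mid <- 100 * sum(runs[runs %in% 2:3]) / sum(runs)
      expect_equal(bp3$singlet_pct + mid + bp3$block4_pct, 100)
    }
  }

  ## terminal gap overhangs are excluded from the default denominator
  aln_ov <- make_alignment("--ACDE", "GGACDE")
  expect_equal(block_partition(aln_ov)$percent_identity, 100)
  expect_equal(block_partition(aln_ov, "all_cols")$percent_identity,
               100 * 4 / 6)
})

test_that("blocky pairs carry block identities and dispersed pairs do not", {
  blocky <- gen_protein_pair(33, 300, 40, "blocky")
  disp <- gen_protein_pair(33, 300, 40, "dispersed")
  bp_b <- block_partition(global_align(blocky$a, blocky$b))
  bp_d <- block_partition(global_align(disp$a, disp$b))
  expect_gt(bp_b$block4_pct, 50)
  expect_lt(bp_d$block4_pct, 10)
})

test_that("the shuffle null separates real homology from background", {
  pair <- gen_protein_pair(55, 200, 45, "blocky")
  settings <- default_aligner_settings()

  ## self-comparison: identity 100, always significant
  self <- shuffle_null(pair$a, pair$a, settings, n_shuffles = 5, seed = 3)
  expect_equal(unname(self$mean_sem_real["mean"]), 100)
  expect_true(self$significant)

  ## shuffled controls put almost no identities in blocks of >= 4
  expect_lt(mean(self$per_setting$null_block4_pct), 5)

  ## blocky real signal is significant over its null
  real <- shuffle_null(pair$a, pair$b, settings, n_shuffles = 5, seed = 3)
  expect_true(real$significant)
  expect_gt(real$mean_sem_real["mean"], real$mean_sem_null["mean"])

  ## seeded runs are bit-reproducible
  again <- shuffle_null(pair$a, pair$b, settings, n_shuffles = 5, seed = 3)
  expect_identical(real, again)

  ## independent random sequences are not significant (calibration)
  n_sig <- 0
  for (i in 1:5) {
    x <- random_protein(150, seed = 600 + i)
    y <- random_protein(150, seed = 700 + i)
    ns <- shuffle_null(x, y, settings, n_shuffles = 5, seed = i)
    n_sig <- n_sig + ns$significant
  }
  expect_lte(n_sig, 1)
})

test_that("null identity is calibrated against a larger monte-carlo run", {
  a <- random_protein(150, seed = 81)
  b <- random_protein(150, seed = 82)
  settings <- default_aligner_settings()[c(1, 3), ]
  small <- shuffle_null(a, b, settings, n_shuffles = 5, seed = 10)
  big <- shuffle_null(a, b, settings, n_shuffles = 40, seed = 11)
  ## per-setting null means from few shuffles sit near the high-n estimate
  for (k in 1:2) {
    expect_lt(abs(small$per_setting$null_identity[k] -
                    big$per_setting$null_identity[k]), 3)
  }
})
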