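test_that("single-sequence composition matches a direct tally", {
  p <- aa_frequencies("SSSS")
  expect_equal(unname(p$frequencies["S"]), 100)
  expect_equal(sum(p$frequencies), 100)

  p2 <- aa_frequencies("SE")
  expect_equal(unname(p2$frequencies[c("S", "E")]), c(50, 50))

  seq <- random_protein(1000, seed = 11)
  p3 <- aa_frequencies(seq)
  tally <- table(factor(strsplit(seq, "")[[1]], levels = AA20))
  expect_equal(unname(p3$frequencies), unname(100 * as.numeric(tally) / 1000))

  ## ambiguity codes are excluded from both numerator and denominator
  p4 <- aa_frequencies("SSXX")
  expect_equal(unname(p4$frequencies["S"]), 100)
  expect_equal(p4$n_excluded, 2L)
  expect_error(aa_frequencies(""), "non-empty")
})

test_that("profile averaging is the unweighted per-sequence mean", {
  p1 <- aa_frequencies(strrep("S", 10), source_label = "long_exon")
  p2 <- aa_frequencies(strrep("E", 30), source_label = "long_exon")
  avg <- average_profiles(list(p1, p2))
  expect_equal(unname(avg$frequencies[c("S", "E")]), c(50, 50))
  expect_equal(avg$n_sequences, 2L)
  expect_equal(average_profiles(list(p1))$frequencies, p1$frequencies)
  p3 <- aa_frequencies("A", source_label = "core")
  expect_error(average_profiles(list(p1, p3)), "mix")

  ## simulated biased polypeptides: set mean within 3 SE of the target
  target <- long_exon_bias_target()
  profs <- lapply(1:11, function(i) {
    sim <- gen_biased_polypeptide(i, 3000, target)
    aa_frequencies(sim$protein, source_label = "long_exon")
  })
  avg11 <- average_profiles(profs)
  n_total <- 11 * 3000
  for (aa in c("S", "E", "A")) {
    p <- target[aa] / 100
    se <- 100 * sqrt(p * (1 - p) / n_total)
    expect_lt(abs(avg11$frequencies[aa] - target[aa]), 3 * se)
  }
})

test_that("top-k fractions are complete, monotone, and biased sets exceed 55%", {
  p <- aa_frequencies(random_protein(500, seed = 2))
  expect_equal(top_k_fraction(p, 20)$percent, 100)
  vals <- vapply(1:20, function(k) top_k_fraction(p, k)$percent, numeric(1))
  expect_true(all(diff(vals) >= 0))

  freqs <- setNames(c(30, 20, rep(50 / 18, 18)),
                    c("S", "E", setdiff(AA20, c("S", "E"))))
  prof <- list(frequencies = freqs[AA20], n_sequences = 1L,
               source_label = "other", n_excluded = 0L)
  class(prof) <- "composition_profile"
  expect_equal(top_k_fraction(prof, 2)$percent, 50)
  expect_setequal(top_k_fraction(prof, 2)$residues, c("S", "E"))

  ## long-exon-like simulated set reproduces the composition bias: top six
  ## residues {S,E,T,D,K,P} above 55% though they use a third of the codons
  sim_profs <- lapply(1:11, function(i)
    aa_frequencies(gen_biased_polypeptide(100 + i, 4000)$protein,
                   source_label = "long_exon"))
  avg <- average_profiles(sim_profs)
  top6 <- top_k_fraction(avg, 6)
  expect_gt(top6$percent, 55)
  expect_setequal(top6$residues, c("S", "E", "T", "D", "K", "P"))
})

test_that("codon fractions agree with exhaustive enumeration of the code", {
  expect_equal(codon_fraction(c("S", "E", "T", "D", "K", "P")),
               100 * 20 / 61)
  expect_equal(codon_fraction(AA20), 100)
  expect_equal(codon_fraction(c("M", "W")), 100 * 2 / 61)
  expect_equal(codon_fraction(character(0)), 0)
  expect_error(codon_fraction("J"), "not standard")

  ## property: arbitrary subsets vs direct enumeration over all 64 codons
  gc <- Biostrings::GENETIC_CODE
  set.seed(19)
  for (i in 1:10) {
    subset <- sample(AA20, sample(1:20, 1))
    n_sense <- sum(gc != "*")
    n_hit <- sum(gc %in% subset)
    expect_equal(codon_fraction(subset), 100 * n_hit / n_sense)
  }
})

test_that("fold enrichment is a self-consistent ratio with flagged zeros", {
  p <- aa_frequencies(random_protein(400, seed = 23), "long_exon")
  self <- fold_enrichment(p, p)
  expect_equal(unname(self$fold), rep(1, 20))

  long <- list(frequencies = setNames(c(40, rep(60 / 19, 19)), AA20),
               n_sequences = 1L, source_label = "long_exon", n_excluded = 0L)
  core <- list(frequencies = setNames(c(10, rep(90 / 19, 19)), AA20),
               n_sequences = 1L, source_label = "core", n_excluded = 0L)
  class(long) <- class(core) <- "composition_profile"
  fe <- fold_enrichment(long, core)
  expect_equal(unname(fe$fold["A"]), 4)

  core0 <- core
  core0$frequencies["W"] <- 0
  fe0 <- fold_enrichment(long, core0)
  expect_true("W" %in% fe0$undefined)
  expect_true(is.na(fe0$fold["W"]))

  ## biased long-exon set vs uniform core: Ser and Glu exceed 2-fold
  long_avg <- average_profiles(lapply(1:6, function(i)
    aa_frequencies(gen_biased_polypeptide(i, 3000)$protein, "long_exon")))
  core_avg <- average_profiles(lapply(1:6, function(i)
    aa_frequencies(random_protein(3000, seed = 300 + i), "core")))
  fe2 <- fold_enrichment(long_avg, core_avg)
  expect_true(all(c("S", "E") %in% fe2$enriched))
})

test_that("the composition matrix orders residues by ascending mean", {
  profs <- lapply(1:5, function(i)
    aa_frequencies(gen_biased_polypeptide(i, 1000)$protein, "long_exon"))
  mat <- composition_matrix(profs)
  expect_equal(dim(mat), c(5L, 20L))
  expect_true(all(diff(colMeans(mat)) >= 0))
  ## the most abundant residue under the long-exon bias ends up last
  expect_equal(colnames(mat)[20], "S")
})
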