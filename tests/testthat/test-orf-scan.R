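test_that("short sequences and stop-free repeats behave at the threshold", {
  expect_equal(nrow(find_orfs(random_dna(200, seed = 1))), 0L)

  g <- c(chr1 = paste(rep("GCA", 200), collapse = ""))
  orfs <- find_orfs(g, min_orf_nt = 300)
  fwd0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_equal(nrow(fwd0), 1L)
  expect_equal(fwd0$start, 0L)
  expect_equal(fwd0$length_nt, 600L)

  ## strict threshold: a 300-nt stop-free run is not kept, a 303-nt one is
  g300 <- c(a = paste(rep("GCA", 100), collapse = ""))
  expect_equal(nrow(find_orfs(g300)[find_orfs(g300)$frame == 0 &
                                      find_orfs(g300)$strand == "+", ]), 0L)
  expect_gt(nrow(find_orfs(g300, strict = FALSE)), 0L)

  expect_error(find_orfs(c(x = "ACGU")), "outside")
  expect_error(find_orfs(c(x = "")), "non-empty")
})

test_that("six-frame scan matches the naive translation oracle", {
  set.seed(101)
  gg <- gen_genome(101, 30000, stop_density = 0.02,
                   planted_orfs = data.frame(position = c(3000, 12000),
                                             length = c(2001, 1200)))
  mine <- find_orfs(gg$genome, min_orf_nt = 300)
  oracle <- oracle_find_orfs(gg$genome, min_orf_nt = 300)
  expect_identical(orf_key(mine), orf_key(oracle))

  ## N-containing codons terminate runs in both routes
  g <- gg$genome
  substr(g[[1]], 5000, 5000) <- "N"
  names(g) <- names(gg$genome)
  expect_identical(orf_key(find_orfs(g)), orf_key(oracle_find_orfs(g)))

  ## planted intervals are recovered exactly
  plant <- mine[mine$start == 3000 & mine$strand == "+", ]
  expect_equal(plant$end, 5001L)
})

test_that("every reported ORF is stop-free when re-translated", {
  gg <- gen_genome(7, 20000, stop_density = 0.03)
  orfs <- find_orfs(gg$genome)
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    seq <- substr(gg$genome[[orfs$contig_id[i]]], orfs$start[i] + 1,
                  orfs$end[i])
    if (orfs$strand[i] == "-")
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_equal(orfs$length_nt[i] %% 3, 0)
  }
})

test_that("scan is strand-symmetric and contigs do not leak across joins", {
  gg <- gen_genome(13, 12000, stop_density = 0.03)
  g <- gg$genome
  len <- nchar(g[[1]])
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g[[1]]))), names(g))
  a <- find_orfs(g)
  b <- find_orfs(rc)
  ## mirror b back onto the forward axis of g
  b_m <- data.frame(start = len - b$end, end = len - b$start,
                    strand = ifelse(b$strand == "+", "-", "+"))
  expect_identical(sort(paste(a$start, a$end, a$strand)),
                   sort(paste(b_m$start, b_m$end, b_m$strand)))

  ## two contigs scanned together give the union of separate scans
  g2 <- c(c1 = substr(g[[1]], 1, 6000), c2 = substr(g[[1]], 6001, len))
  joint <- find_orfs(g2)
  solo <- rbind(find_orfs(g2["c1"]), find_orfs(g2["c2"]))
  expect_identical(orf_key(joint), orf_key(solo))
})

test_that("simple-repeat masking matches a brute-force oracle", {
  ## non-repetitive ORF retained unmasked
  gg <- gen_genome(21, 3000, stop_density = 0)
  orfs <- find_orfs(gg$genome)
  kept <- filter_simple_repeats(orfs, gg$genome)
  expect_equal(nrow(kept), nrow(orfs))
  f0 <- kept[kept$strand == "+" & kept$frame == 0, ]
  expect_equal(f0$masked_fraction, 0)

  ## an ORF that is pure dinucleotide repeat is fully masked and removed
  g_ca <- c(rep1 = paste(rep("CA", 300), collapse = ""))
  o_ca <- find_orfs(g_ca)
  expect_gt(nrow(o_ca), 0)
  expect_equal(nrow(filter_simple_repeats(o_ca, g_ca)), 0L)

  ## planted 120-nt CAG run inside an otherwise clean ORF: masked fraction
  ## agrees with the brute-force mask and the ORF is retained
  set.seed(5)
  clean <- unlist(strsplit(gen_genome(5, 603, stop_density = 0)$genome[[1]],
                           ""))
  clean[241:360] <- rep(c("C", "A", "G"), 40)
  g_mix <- c(mix = paste(clean, collapse = ""))
  o_mix <- find_orfs(g_mix)
  o_mix <- o_mix[o_mix$strand == "+" & o_mix$frame == 0 &
                   o_mix$start == 0, , drop = FALSE]
  if (nrow(o_mix) == 1) {
    filt <- filter_simple_repeats(o_mix, g_mix)
    oracle_mask <- oracle_repeat_mask(g_mix[[1]])
    expect_equal(filt$masked_fraction,
                 mean(oracle_mask[(o_mix$start + 1):o_mix$end]))
    expect_gte(filt$masked_fraction, 120 / o_mix$length_nt * 0.9)
    expect_equal(nrow(filt), 1L)
  }

  ## oracle agreement on random sequence with planted runs of several motifs
  set.seed(31)
  parts <- c(random_dna(400), strrep("ACGTAG", 12), random_dna(300),
             strrep("T", 60), random_dna(200))
  seq <- paste(parts, collapse = "")
  mine <- giantexon:::simple_repeat_mask(seq, 6, 50)
  expect_identical(mine, oracle_repeat_mask(seq))
})

test_that("length summaries and ranking match direct computation", {
  s <- summarize_lengths(data.frame(length_nt = c(300, 300)))
  expect_equal(s$mean_bp, 300)
  expect_equal(s$sd_bp, 0)

  ## geometric background: mean of frame-0 forward ORFs above threshold is
  ## within 3 SE of the memoryless expectation
  stop_density <- 0.03
  gg <- gen_genome(77, 900000, stop_density = stop_density)
  orfs <- find_orfs(gg$genome)
  f0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  ## strict > 300 nt means at least 101 stop-free codons
  m <- 101
  p <- stop_density
  expected_nt <- 3 * (m + (1 - p) / p)
  se_nt <- 3 * sqrt(1 - p) / p / sqrt(nrow(f0))
  expect_lt(abs(mean(f0$length_nt) - expected_nt), 3 * se_nt)

  ## histogram covers the top_k longest
  s2 <- summarize_lengths(orfs, top_k = 100)
  expect_equal(sum(s2$histogram), min(100, nrow(orfs)))
  expect_equal(s2$n_orfs, nrow(orfs))

  ## sample vs population SD flag
  lens <- data.frame(length_nt = c(310, 400, 520))
  expect_equal(summarize_lengths(lens, sd_type = "sample")$sd_bp,
               sd(c(310, 400, 520)))

  ## ranking: maximum is rank 1; rank equals a linear-scan count; monotone
  all_len <- sort(sample(303:5000, 500), decreasing = TRUE)
  summ <- summarize_lengths(data.frame(length_nt = all_len))
  expect_equal(rank_query(max(all_len), summ, all_len)$rank, 1L)
  set.seed(8)
  for (q in sample(all_len, 5)) {
    r <- rank_query(q, summ, all_len)
    expect_equal(r$rank, 1L + sum(all_len > q))
  }
  r_lo <- rank_query(1000, summ, all_len)
  r_hi <- rank_query(2000, summ, all_len)
  expect_lte(r_hi$rank, r_lo$rank)
  expect_gte(r_hi$z_score, r_lo$z_score)
  expect_error(rank_query(0, summ, all_len), "positive")
})
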