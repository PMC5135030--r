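## Seeded generators producing inputs with the statistical structure each
## analysis assumes. Every generator draws from its own RNG stream derived
## from (seed, kind) — adding generators never perturbs existing fixtures —
## and returns a machine-readable truth record alongside the data.

SENSE_CODONS <- NULL  # initialized lazily (needs Biostrings data)

#' @noRd
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulate a genome with a geometric ORF-length background and planted ORFs
#'
#' Background sequence is drawn codon-wise: each codon is a stop codon with
#' probability `stop_density`, otherwise a uniform sense codon, so frame-0
#' forward stop-free runs have a geometric length distribution with mean
#' about `3 / stop_density` nt. Planted intervals are overwritten with
#' stop-free (frame-0 forward) codons and bounded by stop codons, so
#' [find_orfs()] recovers each plant as exactly its interval.
#'
#' @param seed integer seed.
#' @param length_nt genome length in nt (rounded down to whole codons).
#' @param stop_density per-codon stop probability in the background (0-1).
#' @param planted_orfs optional data frame / matrix with columns `position`
#'   (0-based, multiple of 3) and `length` (multiple of 3); intervals (with
#'   their bounding stop codons) must be non-overlapping and in range.
#' @param contig_id contig name.
#' @return list with `genome` (named character vector, one contig) and
#'   `truth` (data frame `start`, `end` of planted ORFs).
#' @export
gen_genome <- function(seed, length_nt, stop_density,
                       planted_orfs = NULL, contig_id = "sim_contig") {
  stopifnot(length_nt >= 3, stop_density >= 0, stop_density <= 1)
  n_codons <- length_nt %/% 3L
  plants <- normalize_plants(planted_orfs, n_codons)
  with_gen_seed(seed, "genome", {
    sense <- sense_codons()
    is_stop <- runif(n_codons) < stop_density
    codons <- character(n_codons)
    codons[!is_stop] <- sample(sense, sum(!is_stop), replace = TRUE)
    codons[is_stop] <- sample(STOP_CODONS, sum(is_stop), replace = TRUE)
    if (nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        c0 <- plants$position[i] %/% 3L        # first codon (0-based)
        nc <- plants$length[i] %/% 3L
        codons[(c0 + 1L):(c0 + nc)] <- sample(sense, nc, replace = TRUE)
        if (c0 >= 1L) codons[c0] <- sample(STOP_CODONS, 1L)
        if (c0 + nc < n_codons) codons[c0 + nc + 1L] <-
            sample(STOP_CODONS, 1L)
      }
    }
    genome <- stats::setNames(paste(codons, collapse = ""), contig_id)
    truth <- data.frame(start = plants$position,
                        end = plants$position + plants$length)
    list(genome = genome, truth = truth)
  })
}

#' @noRd
normalize_plants <- function(planted_orfs, n_codons) {
  if (is.null(planted_orfs) ||
      (is.data.frame(planted_orfs) && !nrow(planted_orfs)))
    return(data.frame(position = integer(), length = integer()))
  plants <- as.data.frame(planted_orfs)
  stopifnot(all(c("position", "length") %in% names(plants)))
  if (any(plants$position %% 3 != 0) || any(plants$length %% 3 != 0))
    stop("planted positions and lengths must be multiples of 3",
         call. = FALSE)
  if (any(plants$length < 3) || any(plants$position < 0) ||
      any(plants$position + plants$length > 3L * n_codons))
    stop("planted interval out of range", call. = FALSE)
  plants <- plants[order(plants$position), , drop = FALSE]
  ## bounding stop codons must not collide either
  if (nrow(plants) > 1) {
    lo <- plants$position - 3L
    hi <- plants$position + plants$length + 3L
    if (any(lo[-1] < hi[-nrow(plants)]))
      stop("planted intervals overlap", call. = FALSE)
  }
  plants
}

#' Simulate an annotated ankyrin locus
#'
#' Builds a contig carrying an ankyrin-like exon structure (core exons, two
#' UPA exons, and — except where noted — two death-domain exons) over a
#' stop-dense background (per-codon stop probability 0.05, so background
#' ORFs stay well below 1 kb), and plants stop-free long ORFs according to
#' the layout:
#'
#' * `cnidarian_no_long_exon`: nothing planted; [scan_locus()] should
#'   certify absence.
#' * `upstream_of_DD`: one 5,001-nt ORF between the UPA and DD exons
#'   (the chordate arrangement).
#' * `downstream_of_DD`: one 5,001-nt ORF after the DD exons (the
#'   protostome/echinoderm arrangement).
#' * `tandem`: two ORFs (4,002 and 5,001 nt) after the DD exons separated by
#'   an intron-sized gap (the fly L/XL-style pair).
#'
#' @param seed integer seed.
#' @param layout one of the four layouts above.
#' @param strand `"+"` (default) or `"-"`; the `"-"` locus is the exact
#'   reverse complement with mirrored annotation.
#' @return list with `genome`, `locus` (a [locus_annotation()]), and `truth`
#'   (list: `layout`, `absence`, and data frame `calls` with the expected
#'   `start`, `end`, `position_vs_DD`).
#' @export
gen_locus <- function(seed,
                      layout = c("cnidarian_no_long_exon", "upstream_of_DD",
                                 "downstream_of_DD", "tandem"),
                      strand = c("+", "-")) {
  layout <- match.arg(layout)
  strand <- match.arg(strand)

  ## segment plan on the forward axis (lengths nt, all multiples of 3)
  exon_len <- 150L
  intron_len <- 300L
  plan <- list()
  add <- function(kind, len) plan[[length(plan) + 1L]] <<-
    list(kind = kind, len = as.integer(len))
  add("flank", 600L)
  for (i in 1:6) { add("exon", exon_len); add("intron", intron_len) }
  add("exon", exon_len); add("intron", intron_len)   # UPA exon 1
  add("exon", exon_len)                              # UPA exon 2
  mid_plants <- switch(layout, upstream_of_DD = 5001L, NULL)
  add("intron", 900L)
  if (!is.null(mid_plants)) { add("plant", mid_plants); add("intron", 900L) }
  add("exon", exon_len); add("intron", intron_len)   # DD exon 1
  add("exon", exon_len)                              # DD exon 2
  add("intron", 900L)
  if (layout == "downstream_of_DD") { add("plant", 5001L); add("intron", 900L) }
  if (layout == "tandem") {
    add("plant", 4002L); add("intron", 501L); add("plant", 5001L)
    add("intron", 900L)
  }
  add("downstream_gene", 600L)

  pos <- 0L
  exons <- NULL
  plants <- NULL
  downstream_gene_start <- NULL
  for (seg in plan) {
    if (seg$kind == "exon") exons <- rbind(exons, c(pos, pos + seg$len))
    if (seg$kind == "plant") plants <- rbind(plants, c(pos, seg$len))
    if (seg$kind == "downstream_gene") downstream_gene_start <- pos
    pos <- pos + seg$len
  }
  total_len <- pos
  planted_orfs <- if (is.null(plants)) NULL else
    data.frame(position = plants[, 1], length = plants[, 2])

  gg <- gen_genome(seed, total_len, stop_density = 0.05,
                   planted_orfs = planted_orfs, contig_id = "sim_locus")

  n_ex <- nrow(exons)
  domain_map <- list(ANK_REPEATS = 1:4, ZU5a = 5L, ZU5b = 6L,
                     UPA = c(7L, 8L), DD = c(9L, 10L))
  locus <- locus_annotation("sim_locus", "+", exons, domain_map,
                            downstream_gene_start)

  truth_calls <- if (is.null(plants)) {
    data.frame(start = integer(), end = integer(),
               position_vs_DD = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(start = plants[, 1], end = plants[, 1] + plants[, 2],
               position_vs_DD = if (layout == "upstream_of_DD")
                 "upstream_of_DD" else "downstream_of_DD",
               stringsAsFactors = FALSE)
  }

  out <- list(genome = gg$genome, locus = locus,
              truth = list(layout = layout, absence = is.null(plants),
                           calls = truth_calls))
  if (strand == "-") out <- mirror_locus_sim(out)
  out
}

## reverse-complement a simulated locus: coordinates x -> L - x, strand "-"
#' @noRd
mirror_locus_sim <- function(sim) {
  L <- nchar(sim$genome[[1L]])
  genome <- stats::setNames(revcomp(sim$genome[[1L]]), names(sim$genome))
  loc <- sim$locus
  exons <- cbind(L - loc$exons[, "end"], L - loc$exons[, "start"])
  ## transcription order is preserved by keeping row order (now descending
  ## genomic starts, which locus_annotation expects on "-")
  dgs <- if (is.null(loc$downstream_gene_start)) NULL else
    L - loc$downstream_gene_start
  locus <- locus_annotation(loc$contig_id, "-", exons, loc$domain_exon_map,
                            dgs)
  calls <- sim$truth$calls
  if (nrow(calls)) {
    new_start <- L - calls$end
    calls$end <- L - calls$start
    calls$start <- new_start
    calls <- calls[order(calls$start), , drop = FALSE]
    rownames(calls) <- NULL
  }
  sim$genome <- genome
  sim$locus <- locus
  sim$truth$calls <- calls
  sim
}

#' Simulate a protein pair with controlled identity structure
#'
#' Generates a random protein `a` and a same-length partner `b` that is
#' identical to `a` at a controlled fraction of positions and differs
#' everywhere else. `blocky` arranges the identical positions in contiguous
#' runs of at least 4 (mimicking genuinely homologous sequence); `dispersed`
#' scatters them as isolated singlets (mimicking the chance matches of a
#' shuffled control). For `dispersed`, `identity_pct` must not exceed 50%.
#'
#' @param seed integer seed.
#' @param length sequence length (aa).
#' @param identity_pct percent identical positions (0-100).
#' @param block_structure `"blocky"` or `"dispersed"`.
#' @return list with `a`, `b`, and `truth` (list: `identity_positions`,
#'   `identity_pct`, `block_structure`).
#' @export
gen_protein_pair <- function(seed, length, identity_pct,
                             block_structure = c("blocky", "dispersed")) {
  block_structure <- match.arg(block_structure)
  stopifnot(length >= 10, identity_pct >= 0, identity_pct <= 100)
  n_id <- round(length * identity_pct / 100)
  with_gen_seed(seed, "protein_pair", {
    a_chars <- sample(AA_ALPHABET, length, replace = TRUE)
    if (n_id >= length) {
      a <- paste(a_chars, collapse = "")
      return(list(a = a, b = a,
                  truth = list(identity_positions = seq_len(length),
                               identity_pct = 100,
                               block_structure = block_structure)))
    }
    id_pos <- if (n_id == 0) integer(0)
    else if (block_structure == "blocky") {
      blocks <- c(rep(8L, n_id %/% 8L))
      rem <- n_id %% 8L
      if (rem >= 4L) blocks <- c(blocks, rem)
      else if (rem > 0L && length(blocks)) blocks[1L] <- blocks[1L] + rem
      else if (rem > 0L) blocks <- 4L  # tiny n_id: one minimal block
      ## distribute the non-identity slack into gaps around the blocks,
      ## interior gaps >= 1 so blocks stay separate runs
      k <- length(blocks)
      slack <- length - sum(blocks) - (k - 1L)
      extra <- if (k + 1L > 1L) tabulate(sample.int(k + 1L, slack,
                                                    replace = TRUE),
                                         nbins = k + 1L) else slack
      gaps <- c(extra[1L], extra[seq_len(k - 1L) + 1L] + 1L)
      starts <- cumsum(gaps) + c(0L, cumsum(blocks[-k])) + 1L
      unlist(mapply(function(s, l) s:(s + l - 1L), starts, blocks,
                    SIMPLIFY = FALSE))
    } else {
      if (n_id > (length + 1L) %/% 2L)
        stop("dispersed identities need identity_pct <= 50%", call. = FALSE)
      sort(sample.int(length - n_id + 1L, n_id)) + seq_len(n_id) - 1L
    }
    b_chars <- vapply(seq_len(length), function(i) {
      if (i %in% id_pos) a_chars[i]
      else sample(setdiff(AA_ALPHABET, a_chars[i]), 1L)
    }, character(1))
    list(a = paste(a_chars, collapse = ""),
         b = paste(b_chars, collapse = ""),
         truth = list(identity_positions = as.integer(id_pos),
                      identity_pct = identity_pct,
                      block_structure = block_structure))
  })
}

#' Composition target resembling ankyrin long-exon polypeptides
#'
#' A percent-composition vector with Ser + Glu near 25% and the top six
#' residues (Ser, Glu, Thr, Asp, Lys, Pro) near 56%, the bias shared by
#' long-exon polypeptides across bilaterians; the remaining 14 residues
#' share the rest uniformly.
#'
#' @return named numeric 20-vector summing to 100.
#' @export
long_exon_bias_target <- function() {
  target <- stats::setNames(rep(0, 20), AA_ALPHABET)
  target[c("S", "E", "T", "D", "K", "P")] <- c(13.5, 11.5, 8.5, 8, 7.5, 7)
  rest <- setdiff(AA_ALPHABET, c("S", "E", "T", "D", "K", "P"))
  target[rest] <- (100 - sum(target)) / length(rest)
  target
}

#' Simulate a polypeptide with a specified composition bias
#'
#' Residues are drawn i.i.d. from `target_frequencies` (a multinomial
#' draw), so observed per-residue frequencies converge on the target with
#' standard error `sqrt(p * (1 - p) / length)`.
#'
#' @param seed integer seed.
#' @param length sequence length (aa).
#' @param target_frequencies named non-negative vector over (a subset of)
#'   the 20 standard residues; normalized internally.
#' @return list with `protein` and `truth` (the normalized target, percent).
#' @export
gen_biased_polypeptide <- function(seed, length,
                                   target_frequencies = long_exon_bias_target()) {
  stopifnot(length >= 1, is.numeric(target_frequencies),
            !is.null(names(target_frequencies)),
            all(target_frequencies >= 0), sum(target_frequencies) > 0)
  bad <- setdiff(names(target_frequencies), AA_ALPHABET)
  if (length(bad))
    stop("target names are not standard residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  p <- target_frequencies / sum(target_frequencies)
  with_gen_seed(seed, "biased_polypeptide", {
    chars <- sample(names(p), length, replace = TRUE, prob = p)
    target <- stats::setNames(rep(0, 20), AA_ALPHABET)
    target[names(p)] <- 100 * p
    list(protein = paste(chars, collapse = ""), truth = list(target = target))
  })
}

#' Simulate a tandem-repeat array with mutational noise
#'
#' A random repeat unit copied `n_copies` times in tandem, each residue
#' independently substituted with probability `mutation_rate`, embedded in
#' random flanking sequence.
#'
#' @param seed integer seed.
#' @param unit_length repeat-unit length (nt or aa).
#' @param n_copies number of tandem copies.
#' @param mutation_rate per-position substitution probability.
#' @param alphabet `"aa"` or `"nt"`.
#' @param flank_length random flank on each side.
#' @return list with `sequence`, and `truth` (list: `unit`, `unit_length`,
#'   `n_copies`, `start`, `end` — 0-based half-open array span).
#' @export
gen_repeat_array <- function(seed, unit_length, n_copies,
                             mutation_rate = 0.05,
                             alphabet = c("aa", "nt"), flank_length = 200) {
  alphabet <- match.arg(alphabet)
  stopifnot(unit_length >= 1, n_copies >= 2,
            mutation_rate >= 0, mutation_rate < 1, flank_length >= 0)
  letters_ <- if (alphabet == "aa") AA_ALPHABET else c("A", "C", "G", "T")
  with_gen_seed(seed, "repeat_array", {
    unit <- sample(letters_, unit_length, replace = TRUE)
    arr <- rep(unit, n_copies)
    mut <- runif(length(arr)) < mutation_rate
    arr[mut] <- vapply(arr[mut], function(x)
      sample(setdiff(letters_, x), 1L), character(1))
    fl1 <- sample(letters_, flank_length, replace = TRUE)
    fl2 <- sample(letters_, flank_length, replace = TRUE)
    list(sequence = paste(c(fl1, arr, fl2), collapse = ""),
         truth = list(unit = paste(unit, collapse = ""),
                      unit_length = unit_length, n_copies = n_copies,
                      start = flank_length,
                      end = flank_length + unit_length * n_copies))
  })
}

#' Simulate a FRAP trace with known mobile fraction
#'
#' The underlying corrected ratio follows
#' `r(t) = r0 + (1 - r0) * mobile * (1 - exp(-(t - t_bleach) / tau))` after
#' the bleach (with `r0 = 1 - bleach_depth`) and 1 before it. Bleached and
#' reference channels share a slow acquisition-photobleaching decay and
#' carry independent multiplicative Gaussian noise, so the double
#' normalization in [normalize_frap()] must undo both. Defaults lay out a
#' ~2-minute movie (5 s baseline, 130 s total at 2 Hz) so the standard
#' 110-120 s plateau window falls late on the recovery curve.
#'
#' @param seed integer seed.
#' @param mobile_fraction mobile fraction in 0-1; the true recovery plateau
#'   is `100 * mobile_fraction` percent.
#' @param tau_s recovery time constant (s).
#' @param noise_cv coefficient of variation of the per-channel noise.
#' @param duration_s,dt_s movie length and sampling interval (s).
#' @param bleach_time_s bleach time (s); samples at or after it are
#'   post-bleach.
#' @param bleach_depth fraction of bleached-region signal removed by the
#'   bleach (0-1).
#' @return list with `trace` (a [frap_trace()]) and `truth` (list of the
#'   generating parameters).
#' @export
gen_frap_trace <- function(seed, mobile_fraction, tau_s, noise_cv = 0.01,
                           duration_s = 130, dt_s = 0.5, bleach_time_s = 5,
                           bleach_depth = 0.7) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau_s > 0,
            noise_cv >= 0, bleach_depth > 0, bleach_depth <= 1,
            bleach_time_s > dt_s, duration_s > bleach_time_s)
  with_gen_seed(seed, "frap_trace", {
    time_s <- seq(0, duration_s, by = dt_s)
    post <- time_s >= bleach_time_s
    r0 <- 1 - bleach_depth
    r <- rep(1, length(time_s))
    r[post] <- r0 + (1 - r0) * mobile_fraction *
      (1 - exp(-(time_s[post] - bleach_time_s) / tau_s))
    reference <- 1000 * exp(-time_s / 600)        # slow acquisition bleach
    bleach <- 0.8 * r * reference
    if (noise_cv > 0) {
      bleach <- bleach * (1 + rnorm(length(time_s), 0, noise_cv))
      reference <- reference * (1 + rnorm(length(time_s), 0, noise_cv))
    }
    list(trace = frap_trace(time_s, bleach, reference, bleach_time_s),
         truth = list(mobile_fraction = mobile_fraction, tau_s = tau_s,
                      noise_cv = noise_cv, bleach_depth = bleach_depth,
                      bleach_time_s = bleach_time_s))
  })
}

#' Simulate a multiple alignment with known column conservation
#'
#' Builds columns with an exact largest identical-residue class for each
#' requested agreement level (the shared residue is assigned to a random row
#' subset of that size; remaining rows receive mutually distinct other
#' residues), fills any remaining columns with uniform random residues, and
#' shuffles column order. Random columns can only add to the per-level
#' counts, so observed counts are >= the specification at each level.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols alignment dimensions (`n_rows` between 2 and 20).
#' @param conservation_spec named vector mapping agreement level `m`
#'   (as character, e.g. `"4"`) to the number of columns constructed with
#'   exactly that largest-class size; must be non-empty and sum to at most
#'   `n_cols`.
#' @return list with `msa` (named character vector) and `truth` (list:
#'   `conservation_spec`).
#' @export
gen_msa <- function(seed, n_rows, n_cols, conservation_spec) {
  stopifnot(n_rows >= 2, n_rows <= 20, n_cols >= 1)
  if (is.null(conservation_spec) || !length(conservation_spec) ||
      sum(conservation_spec) == 0)
    stop("conservation_spec must be a non-empty named count vector",
         call. = FALSE)
  m_levels <- as.integer(names(conservation_spec))
  if (anyNA(m_levels) || any(m_levels < 1L) || any(m_levels > n_rows))
    stop("conservation_spec names must be agreement levels 1..n_rows",
         call. = FALSE)
  if (sum(conservation_spec) > n_cols)
    stop("conservation_spec exceeds n_cols", call. = FALSE)
  with_gen_seed(seed, "msa", {
    cols <- vector("list", n_cols)
    idx <- 1L
    for (k in seq_along(m_levels)) {
      m <- m_levels[k]
      for (j in seq_len(conservation_spec[k])) {
        res <- sample(AA_ALPHABET, 1L)
        col <- rep(NA_character_, n_rows)
        share <- sample.int(n_rows, m)
        col[share] <- res
        others <- sample(setdiff(AA_ALPHABET, res), n_rows - m)
        col[-share] <- others
        cols[[idx]] <- col
        idx <- idx + 1L
      }
    }
    while (idx <= n_cols) {
      cols[[idx]] <- sample(AA_ALPHABET, n_rows, replace = TRUE)
      idx <- idx + 1L
    }
    mat <- do.call(cbind, cols)[, sample.int(n_cols), drop = FALSE]
    msa <- stats::setNames(apply(mat, 1, paste, collapse = ""),
                           paste0("seq_", seq_len(n_rows)))
    list(msa = msa, truth = list(conservation_spec = conservation_spec))
  })
}
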