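#' Find stop-free open reading frames in all six frames
#'
#' Enumerates every maximal stop-free codon run in the three forward and three
#' reverse frames of each contig. An ORF here is a run of consecutive codons
#' containing no stop codon (standard genetic code); no start codon is
#' required. Runs are bounded by stop codons, contig ends, and codons
#' containing `N` (treated conservatively as run terminators).
#'
#' By default the length threshold is strict (`length_nt > min_orf_nt`, the
#' "> 300 nucleotides" convention), which with codon granularity keeps ORFs of
#' at least `min_orf_nt + 3` nt; set `strict = FALSE` for an inclusive
#' (`>=`) threshold.
#'
#' @param genome named character vector of contig sequences (alphabet
#'   `A,C,G,T,N`), a `DNAStringSet`, or a single string.
#' @param min_orf_nt minimum ORF length in nucleotides; must be a positive
#'   multiple of 3.
#' @param strict logical; if `TRUE` (default) keep ORFs with
#'   `length_nt > min_orf_nt`, otherwise `length_nt >= min_orf_nt`.
#' @return data frame of class `orf_set` with columns `contig_id`, `start`,
#'   `end` (0-based half-open on the forward strand), `strand` (`+`/`-`),
#'   `frame` (0-2 on the ORF's own strand), `length_nt`, `masked_fraction`
#'   (0 until [filter_simple_repeats()] is applied). The stop codon bounding a
#'   run is not part of the ORF and is not counted in `length_nt`.
#' @examples
#' g <- c(chr1 = paste(rep("GCA", 200), collapse = ""))
#' find_orfs(g, min_orf_nt = 300)
#' @seealso [filter_simple_repeats()], [summarize_lengths()], [rank_query()]
#' @export
find_orfs <- function(genome, min_orf_nt = 300, strict = TRUE) {
  genome <- as_genome(genome)
  if (!is.numeric(min_orf_nt) || length(min_orf_nt) != 1L || min_orf_nt < 3 ||
      min_orf_nt %% 3 != 0)
    stop("min_orf_nt must be a positive multiple of 3", call. = FALSE)

  out <- lapply(names(genome), function(cid) {
    seq_fwd <- genome[[cid]]
    len <- nchar(seq_fwd)
    res <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
      for (frame in 0:2) {
        runs <- stop_free_runs(s, frame)
        if (!nrow(runs)) next
        keep <- if (strict) runs$length_nt > min_orf_nt else
          runs$length_nt >= min_orf_nt
        runs <- runs[keep, , drop = FALSE]
        if (!nrow(runs)) next
        if (strand == "-") {
          ## map coordinates from the reverse-complement axis back to forward
          new_start <- len - runs$end
          runs$end <- len - runs$start
          runs$start <- new_start
        }
        res[[length(res) + 1L]] <- data.frame(
          contig_id = cid, start = runs$start, end = runs$end,
          strand = strand, frame = frame, length_nt = runs$length_nt,
          masked_fraction = 0, stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      length_nt = integer(), masked_fraction = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$contig_id, out$start, out$end, out$strand, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("orf_set", "data.frame")
  out
}

## Maximal stop-free codon runs of one frame of one strand-oriented sequence.
## Returns 0-based half-open coordinates on that sequence's own axis.
#' @noRd
stop_free_runs <- function(s, frame) {
  len <- nchar(s)
  n_codons <- (len - frame) %/% 3L
  empty <- data.frame(start = integer(), end = integer(),
                      length_nt = integer())
  if (n_codons < 1L) return(empty)
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L  # 1-based
  codons <- substring(s, starts, starts + 2L)
  ok <- !(codons %in% STOP_CODONS) & !grepl("N", codons, fixed = TRUE)
  r <- rle(ok)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  good <- which(r$values)
  if (!length(good)) return(empty)
  ci <- starts_idx[good]
  cj <- ends_idx[good]
  data.frame(start = frame + 3L * (ci - 1L),
             end = frame + 3L * cj,
             length_nt = 3L * (cj - ci + 1L))
}

#' Mask simple tandem repeats and drop heavily masked ORFs
#'
#' Detects exact tandem runs of any motif of 1 to `motif_max_nt` nucleotides
#' spanning at least `min_run_nt` nt (by period-`m` self-match), records the
#' masked fraction of each ORF, and removes ORFs whose masked fraction
#' exceeds `max_masked_fraction`. This implements the filter that discards
#' ORFs interrupted by long stretches of simple repeats.
#'
#' @param orfs an `orf_set` from [find_orfs()].
#' @param genome the same genome the ORFs were found on.
#' @param motif_max_nt maximum repeat-unit length considered (nt).
#' @param min_run_nt minimum span of a tandem run to be masked (nt).
#' @param max_masked_fraction ORFs with a larger masked fraction are dropped.
#' @return the filtered `orf_set` with `masked_fraction` filled in.
#' @export
filter_simple_repeats <- function(orfs, genome, motif_max_nt = 6,
                                  min_run_nt = 50, max_masked_fraction = 0.5) {
  stopifnot(inherits(orfs, "data.frame"))
  genome <- as_genome(genome)
  if (!all(orfs$contig_id %in% names(genome)))
    stop("orfs refer to contigs absent from genome", call. = FALSE)
  if (!nrow(orfs)) return(orfs)

  masks <- lapply(genome, simple_repeat_mask, motif_max_nt = motif_max_nt,
                  min_run_nt = min_run_nt)
  orfs$masked_fraction <- vapply(seq_len(nrow(orfs)), function(i) {
    m <- masks[[orfs$contig_id[i]]]
    mean(m[(orfs$start[i] + 1L):orfs$end[i]])
  }, numeric(1))
  out <- orfs[orfs$masked_fraction <= max_masked_fraction, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orf_set", "data.frame")
  out
}

## Logical mask over one contig: TRUE where the base lies inside an exact
## tandem run of period m <= motif_max_nt spanning >= min_run_nt nt.
#' @noRd
simple_repeat_mask <- function(sequence, motif_max_nt, min_run_nt) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  mask <- logical(len)
  for (m in seq_len(motif_max_nt)) {
    if (len <= m) break
    eq <- chars[seq_len(len - m)] == chars[(m + 1L):len]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + m) >= min_run_nt)
    for (k in hit) mask[starts[k]:(ends[k] + m)] <- TRUE
  }
  mask
}

#' Summarize an ORF length distribution
#'
#' Computes the census statistics used to place a query ORF in context: the
#' number of qualifying ORFs, their mean and standard deviation in bp, and a
#' 250-bp histogram of the `top_k` longest ORFs.
#'
#' @param orfs an `orf_set` (or a data frame with a `length_nt` column).
#' @param top_k number of largest ORFs to histogram.
#' @param bin_bp histogram bin width in bp.
#' @param sd_type `"population"` (default; divisor n) or `"sample"`
#'   (divisor n - 1).
#' @return list of class `orf_length_summary` with elements `n_orfs`,
#'   `mean_bp`, `sd_bp`, `histogram` (counts named by bin lower bound),
#'   `top_k`, `bin_bp`, `sd_type`. With no ORFs, `mean_bp`/`sd_bp` are `NA`.
#' @export
summarize_lengths <- function(orfs, top_k = 1000, bin_bp = 250,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  lens <- as.numeric(orfs$length_nt)
  n <- length(lens)
  if (n == 0L) {
    out <- list(n_orfs = 0L, mean_bp = NA_real_, sd_bp = NA_real_,
                histogram = integer(0), top_k = top_k, bin_bp = bin_bp,
                sd_type = sd_type)
    class(out) <- "orf_length_summary"
    return(out)
  }
  mean_bp <- mean(lens)
  sd_bp <- if (n == 1L) 0 else if (sd_type == "sample") stats::sd(lens) else
    sqrt(mean((lens - mean_bp)^2))
  top <- sort(lens, decreasing = TRUE)[seq_len(min(top_k, n))]
  bins <- floor(top / bin_bp) * bin_bp
  histogram <- table(factor(bins, levels = seq(min(bins), max(bins), bin_bp)))
  out <- list(n_orfs = n, mean_bp = mean_bp, sd_bp = sd_bp,
              histogram = histogram, top_k = top_k, bin_bp = bin_bp,
              sd_type = sd_type)
  class(out) <- "orf_length_summary"
  out
}

#' @export
print.orf_length_summary <- function(x, ...) {
  cat("ORF length summary\n")
  cat(sprintf("  n ORFs : %d\n", x$n_orfs))
  if (x$n_orfs > 0)
    cat(sprintf("  length : %.0f +/- %.0f (%s S.D.) bp\n",
                x$mean_bp, x$sd_bp, x$sd_type))
  cat(sprintf("  histogram: top %d ORFs in %d-bp bins (%d bins)\n",
              x$top_k, x$bin_bp, length(x$histogram)))
  invisible(x)
}

#' Rank a query ORF against a genome-wide length distribution
#'
#' Places a query ORF length by rank (1 + number of ORFs strictly longer,
#' so ties receive the minimum rank) and z-score
#' `(query - mean) / sd` against the census in `summary`.
#'
#' @param query_length_nt query ORF length in nt (> 0).
#' @param summary an `orf_length_summary` from [summarize_lengths()].
#' @param all_lengths the lengths (nt) of all ORFs in the census.
#' @return list of class `rank_result` with `query_length_nt`, `rank`,
#'   `z_score`.
#' @examples
#' s <- list(mean_bp = 436, sd_bp = 308)
#' class(s) <- "orf_length_summary"
#' rank_query(13344, s, c(436, 13344, 14000))
#' @export
rank_query <- function(query_length_nt, summary, all_lengths) {
  if (!is.numeric(query_length_nt) || length(query_length_nt) != 1L ||
      query_length_nt <= 0)
    stop("query_length_nt must be a single positive number", call. = FALSE)
  if (!inherits(summary, "orf_length_summary"))
    stop("summary must be an orf_length_summary", call. = FALSE)
  if (is.na(summary$sd_bp) || summary$sd_bp <= 0)
    stop("z-score undefined: summary sd_bp must be > 0", call. = FALSE)
  out <- list(query_length_nt = query_length_nt,
              rank = 1L + sum(all_lengths > query_length_nt),
              z_score = (query_length_nt - summary$mean_bp) / summary$sd_bp)
  class(out) <- "rank_result"
  out
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("query ORF %d nt: rank %d, %.1f S.D. above the genome mean\n",
              as.integer(x$query_length_nt), x$rank, x$z_score))
  invisible(x)
}
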