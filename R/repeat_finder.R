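#' Detect internal tandem-repeat arrays
#'
#' Finds arrays of approximately repeated units inside a nucleotide or
#' polypeptide sequence by period detection on self-matches: for every
#' candidate period p, positions where the sequence matches itself at lag p
#' are located, stretches where the trailing window of p lags stays above
#' the identity threshold are extended into candidate arrays, and
#' overlapping candidates across periods (a true period always echoes at its
#' multiples) are merged to the highest-scoring period, scored by
#' `copy_number * mean_unit_identity`. Arrays below the copy-number or
#' identity thresholds are suppressed. Defaults reflect the ranges observed
#' for ankyrin long-exon arrays (roughly 5 to >160 copies of 36-228 bp
#' units).
#'
#' @param sequence nucleotide or amino-acid string.
#' @param min_copies minimum copies for a reported array.
#' @param min_unit,max_unit candidate unit-length range (nt or aa).
#' @param min_unit_identity minimum mean identity (%) between consecutive
#'   units.
#' @return data frame of class `repeat_array_set` with columns
#'   `unit_length`, `copy_number`, `start`, `end` (0-based half-open),
#'   `mean_unit_identity`. Arrays are non-overlapping, best score first.
#' @examples
#' arr <- paste(rep("MKLVNSEQDP", 8), collapse = "")
#' detect_repeats(arr, min_unit = 5, max_unit = 20)
#' @export
detect_repeats <- function(sequence, min_copies = 5, min_unit = 10,
                           max_unit = 300, min_unit_identity = 70) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  stopifnot(min_copies >= 2, min_unit >= 1, max_unit >= min_unit,
            min_unit_identity > 0, min_unit_identity <= 100)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  len <- length(chars)
  if (len < min_copies * min_unit) return(empty_repeat_set())
  thr <- min_unit_identity / 100

  cand <- list()
  for (p in seq(min_unit, min(max_unit, len %/% 2))) {
    eq <- chars[seq_len(len - p)] == chars[(p + 1L):len]
    if (length(eq) < p) next
    sm <- as.numeric(stats::filter(eq, rep(1 / p, p), sides = 1))
    ok <- !is.na(sm) & sm >= thr
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts[k] - p + 1L   # first lag-index covered by the run
      i2 <- ends[k]
      span_start <- i1           # 1-based in sequence
      span_end <- i2 + p
      copies <- round((span_end - span_start + 1L) / p)
      if (copies < min_copies) next
      ident <- mean(eq[i1:i2])
      if (ident < thr) next
      cand[[length(cand) + 1L]] <- data.frame(
        unit_length = p, copy_number = copies,
        start = span_start - 1L, end = span_end,
        mean_unit_identity = 100 * ident,
        score = copies * ident)
    }
  }
  if (!length(cand)) return(empty_repeat_set())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$unit_length), , drop = FALSE]

  ## greedy merge: keep best-scoring call, drop anything overlapping it
  kept <- cand[0, ]
  while (nrow(cand)) {
    best <- cand[1, , drop = FALSE]
    kept <- rbind(kept, best)
    overlaps <- cand$start < best$end & cand$end > best$start
    cand <- cand[!overlaps, , drop = FALSE]
  }
  kept$score <- NULL
  rownames(kept) <- NULL
  class(kept) <- c("repeat_array_set", "data.frame")
  kept
}

#' @noRd
empty_repeat_set <- function() {
  out <- data.frame(unit_length = integer(), copy_number = integer(),
                    start = integer(), end = integer(),
                    mean_unit_identity = numeric())
  class(out) <- c("repeat_array_set", "data.frame")
  out
}
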