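#' Default grid of aligner settings
#'
#' Six documented (substitution matrix, gap-open, gap-extend) combinations
#' for [global_align()], playing the role of the "different alignment
#' techniques" over which identity statistics are averaged. Varying the
#' matrix series and gap stringency probes how robust a similarity signal is
#' to aligner parameterization while keeping the procedure self-contained
#' and deterministic.
#'
#' @return data frame with columns `id`, `matrix`, `gap_open`, `gap_extend`.
#' @export
default_aligner_settings <- function() {
  data.frame(
    id = c("B62_go10_ge0.5", "B62_go5_ge1", "B45_go10_ge0.5",
           "B80_go10_ge0.5", "PAM250_go10_ge0.5", "PAM70_go10_ge0.5"),
    matrix = c("BLOSUM62", "BLOSUM62", "BLOSUM45", "BLOSUM80",
               "PAM250", "PAM70"),
    gap_open = c(10, 5, 10, 10, 10, 10),
    gap_extend = c(0.5, 1, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

#' @noRd
get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment (end gaps penalized) under an affine
#' gap model where a gap of length L costs `gap_open + L * gap_extend`.
#' Traceback tie-breaking is fixed (diagonal, then gap-in-second, then
#' gap-in-first sequence) so alignments are deterministic.
#'
#' @param a,b amino-acid strings (20 standard residues).
#' @param setting one row of [default_aligner_settings()] (or a list with
#'   `id`, `matrix`, `gap_open`, `gap_extend`), or a setting `id` string.
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` gaps), `score`, `setting_id`.
#' @examples
#' aln <- global_align("ANKYRIN", "ANKYRIN")
#' block_partition(aln)$percent_identity
#' @export
global_align <- function(a, b, setting = default_aligner_settings()[1, ]) {
  a <- check_protein(a, "a", allow_ambiguous = FALSE)
  b <- check_protein(b, "b", allow_ambiguous = FALSE)
  if (is.character(setting) && length(setting) == 1L) {
    grid <- default_aligner_settings()
    if (!setting %in% grid$id)
      stop("unknown setting id: ", setting, call. = FALSE)
    setting <- grid[grid$id == setting, ]
  }
  submat <- get_submat(setting$matrix)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  ia <- match(ca, rownames(submat))
  ib <- match(cb, rownames(submat))
  res <- cpp_affine_align(ia, ib, submat,
                          as.numeric(setting$gap_open),
                          as.numeric(setting$gap_extend))
  aligned_a <- ifelse(res$path_a == 0L, "-", ca[pmax(res$path_a, 1L)])
  aligned_b <- ifelse(res$path_b == 0L, "-", cb[pmax(res$path_b, 1L)])
  out <- list(aligned_a = paste(aligned_a, collapse = ""),
              aligned_b = paste(aligned_b, collapse = ""),
              score = res$score,
              setting_id = as.character(setting$id))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("global alignment (%s), score %.1f, %d columns\n",
              x$setting_id, x$score, nchar(x$aligned_a)))
  n <- nchar(x$aligned_a)
  for (i in seq(1, n, width)) {
    j <- min(i + width - 1, n)
    ca <- substr(x$aligned_a, i, j)
    cb <- substr(x$aligned_b, i, j)
    mid <- paste(ifelse(strsplit(ca, "")[[1]] == strsplit(cb, "")[[1]] &
                          strsplit(ca, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(ca, "\n", mid, "\n", cb, "\n\n", sep = "")
  }
  invisible(x)
}

## column-wise match vector and gap flags for an alignment
#' @noRd
alignment_columns <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("aligned strings differ in length", call. = FALSE)
  list(a = ca, b = cb,
       match = ca == cb & ca != "-",
       gap = ca == "-" | cb == "-")
}

#' Partition aligned identities into singlets and blocks
#'
#' Identity runs are maximal stretches of consecutive alignment columns with
#' identical residues (a gap or mismatch breaks a run). The statistic
#' partitions identities into singlets (runs of length 1) versus blocks of
#' >= 4 consecutive identities; block identities indicate genuine rather
#' than chance similarity, since shuffled-sequence alignments place almost
#' all their identities in singlets.
#'
#' @param aln a `pairwise_alignment`.
#' @param denominator denominator for percent identity:
#'   `"aligned_cols"` (default; alignment columns excluding terminal gap
#'   overhangs), `"shorter"` (length of the shorter input sequence), or
#'   `"all_cols"` (all alignment columns).
#' @return list of class `block_identity_summary`: `percent_identity`,
#'   `n_identities`, `singlet_pct`, `block4_pct` (percent of identities in
#'   runs of length 1 and >= 4 respectively), `run_length_histogram`
#'   (counts named by run length), `denominator`.
#' @export
block_partition <- function(aln,
                            denominator = c("aligned_cols", "shorter",
                                            "all_cols")) {
  denominator <- match.arg(denominator)
  cols <- alignment_columns(aln)
  n_col <- length(cols$match)
  denom <- switch(denominator,
    aligned_cols = {
      non_gap <- which(!cols$gap)
      if (length(non_gap)) max(non_gap) - min(non_gap) + 1L else 0L
    },
    shorter = min(sum(cols$a != "-"), sum(cols$b != "-")),
    all_cols = n_col)
  r <- rle(cols$match)
  runs <- r$lengths[r$values]
  n_id <- sum(runs)
  hist <- if (length(runs)) table(factor(runs, levels = seq_len(max(runs))))
          else table(integer(0))
  out <- list(
    percent_identity = if (denom > 0) 100 * n_id / denom else NA_real_,
    n_identities = n_id,
    singlet_pct = if (n_id > 0) 100 * sum(runs == 1) / n_id else NA_real_,
    block4_pct = if (n_id > 0) 100 * sum(runs[runs >= 4]) / n_id else
      NA_real_,
    run_length_histogram = hist,
    denominator = denominator)
  class(out) <- "block_identity_summary"
  out
}

#' @export
print.block_identity_summary <- function(x, ...) {
  cat(sprintf("identity %.1f%% (%d identities, denominator: %s)\n",
              x$percent_identity, x$n_identities, x$denominator))
  if (x$n_identities > 0)
    cat(sprintf("  singlets %.1f%% | blocks >=4 %.1f%% of identities\n",
                x$singlet_pct, x$block4_pct))
  invisible(x)
}

#' Shuffled-sequence null for pairwise homology
#'
#' Aligns `a` against `b` and against `n_shuffles` residue-permuted copies
#' of `b` (seeded Fisher-Yates shuffle, which preserves composition exactly)
#' under each aligner setting. Real and null per-setting percent identities
#' are compared by a two-sided two-sample t-test; the null block-of->=4
#' percentage is also reported, since true homology concentrates identities
#' in blocks while shuffled controls scatter them as singlets.
#'
#' @param a,b amino-acid strings.
#' @param settings data frame of aligner settings
#'   (default [default_aligner_settings()]; at least 2 rows for a SEM).
#' @param n_shuffles shuffled copies of `b` per setting (>= 1).
#' @param seed integer seed for the shuffles.
#' @param alpha significance level (default 0.05).
#' @param denominator passed to [block_partition()].
#' @return list of class `null_comparison`: `per_setting` (data frame with
#'   real and mean-null identity and block4 percentages per setting),
#'   `mean_sem_real`, `mean_sem_null` (c(mean, sem)), `p_value`,
#'   `significant`, `seed`.
#' @export
shuffle_null <- function(a, b, settings = default_aligner_settings(),
                         n_shuffles = 20, seed = 1, alpha = 0.05,
                         denominator = "aligned_cols") {
  a <- check_protein(a, "a", allow_ambiguous = FALSE)
  b <- check_protein(b, "b", allow_ambiguous = FALSE)
  stopifnot(n_shuffles >= 1, nrow(settings) >= 2)
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  shuffled <- with_gen_seed(seed, "shuffle_null", {
    lapply(seq_len(n_shuffles), function(i)
      paste(sample(cb), collapse = ""))
  })

  rows <- lapply(seq_len(nrow(settings)), function(k) {
    st <- settings[k, ]
    real <- block_partition(global_align(a, b, st), denominator)
    nulls <- lapply(shuffled, function(s)
      block_partition(global_align(a, s, st), denominator))
    data.frame(
      setting_id = as.character(st$id),
      real_identity = real$percent_identity,
      real_block4_pct = real$block4_pct,
      null_identity = mean(vapply(nulls, `[[`, numeric(1),
                                  "percent_identity")),
      null_block4_pct = mean(vapply(nulls, function(n)
        if (is.na(n$block4_pct)) 0 else n$block4_pct, numeric(1))),
      stringsAsFactors = FALSE)
  })
  per_setting <- do.call(rbind, rows)

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  p_value <- tryCatch(
    stats::t.test(per_setting$real_identity,
                  per_setting$null_identity)$p.value,
    error = function(e) {
      ## both groups constant: report rather than crash
      if (isTRUE(all.equal(mean(per_setting$real_identity),
                           mean(per_setting$null_identity)))) 1 else 0
    })
  out <- list(per_setting = per_setting,
              mean_sem_real = c(mean = mean(per_setting$real_identity),
                                sem = sem(per_setting$real_identity)),
              mean_sem_null = c(mean = mean(per_setting$null_identity),
                                sem = sem(per_setting$null_identity)),
              p_value = p_value,
              significant = p_value < alpha,
              alpha = alpha, n_shuffles = n_shuffles, seed = seed)
  class(out) <- "null_comparison"
  out
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "real identity %.1f +/- %.1f%% vs shuffled null %.1f +/- %.1f%% (mean +/- SEM over %d settings)\n",
    x$mean_sem_real["mean"], x$mean_sem_real["sem"],
    x$mean_sem_null["mean"], x$mean_sem_null["sem"],
    nrow(x$per_setting)))
  cat(sprintf("  t-test p = %.3g: %s at alpha = %.2f (%d shuffles, seed %d)\n",
              x$p_value,
              if (x$significant) "significantly above the null" else
                "not significant",
              x$alpha, x$n_shuffles, x$seed))
  invisible(x)
}
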