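#' Amino-acid composition of a polypeptide
#'
#' Percent composition over the 20 standard residues. Ambiguous residues
#' (`X`, `B`, `Z`, `U`, `J`, `O`) and stops are excluded from both numerator
#' and denominator; their count is reported.
#'
#' @param protein amino-acid string.
#' @param source_label provenance tag: `"long_exon"`, `"core"`, or `"other"`.
#' @return list of class `composition_profile` with `frequencies` (named
#'   20-vector of percentages summing to 100), `n_sequences` (1),
#'   `source_label`, `n_excluded`.
#' @examples
#' aa_frequencies("SE")  # Ser 50, Glu 50
#' @export
aa_frequencies <- function(protein,
                           source_label = c("other", "long_exon", "core")) {
  source_label <- match.arg(source_label)
  protein <- check_protein(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  std <- chars %in% AA_ALPHABET
  n_excluded <- sum(!std)
  if (!any(std))
    stop("no standard residues left after excluding ambiguity codes",
         call. = FALSE)
  counts <- table(factor(chars[std], levels = AA_ALPHABET))
  out <- list(frequencies = 100 * as.numeric(counts) / sum(counts),
              n_sequences = 1L, source_label = source_label,
              n_excluded = n_excluded)
  names(out$frequencies) <- AA_ALPHABET
  class(out) <- "composition_profile"
  out
}

#' Average several composition profiles
#'
#' Unweighted per-residue mean over member profiles (each sequence counts
#' equally regardless of length), the convention for averaging composition
#' across a set of long-exon or core polypeptides. A pooled-residue mean
#' (equivalent to concatenating the sequences) is available via
#' `weights`.
#'
#' @param profiles list of `composition_profile`s sharing one `source_label`.
#' @param weights `"equal"` (default, unweighted mean) or `"residues"`
#'   (pool by residue count; requires per-profile residue totals, so only
#'   valid for single-sequence profiles built by [aa_frequencies()] on known
#'   sequences — here approximated by weighting each profile by
#'   `n_sequences`).
#' @return a `composition_profile` with `n_sequences` = total members.
#' @export
average_profiles <- function(profiles, weights = c("equal", "residues")) {
  weights <- match.arg(weights)
  if (!length(profiles))
    stop("need at least one profile", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "composition_profile")))
  labels <- unique(vapply(profiles, `[[`, character(1), "source_label"))
  if (length(labels) != 1L)
    stop("profiles mix source labels: ", paste(labels, collapse = ", "),
         call. = FALSE)
  mat <- vapply(profiles, `[[`, numeric(20), "frequencies")
  w <- if (weights == "equal") rep(1, ncol(mat)) else
    vapply(profiles, `[[`, integer(1), "n_sequences")
  freq <- as.numeric(mat %*% (w / sum(w)))
  names(freq) <- AA_ALPHABET
  out <- list(frequencies = freq,
              n_sequences = sum(vapply(profiles, `[[`, integer(1),
                                       "n_sequences")),
              source_label = labels,
              n_excluded = sum(vapply(profiles, `[[`, numeric(1),
                                      "n_excluded")))
  class(out) <- "composition_profile"
  out
}

#' @export
print.composition_profile <- function(x, digits = 1, ...) {
  cat(sprintf("amino-acid composition (%s, n = %d sequence%s)\n",
              x$source_label, x$n_sequences,
              if (x$n_sequences == 1) "" else "s"))
  print(round(sort(x$frequencies, decreasing = TRUE), digits))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d ambiguous residues excluded)\n", x$n_excluded))
  invisible(x)
}

#' Summed frequency of the k most abundant residues
#'
#' @param profile a `composition_profile`.
#' @param k number of residues, 1-20.
#' @return list with `percent` (sum of the k largest frequencies) and
#'   `residues` (their one-letter codes, most abundant first; ties broken
#'   alphabetically).
#' @examples
#' p <- aa_frequencies(paste(rep("SSSEEETDKPAV", 10), collapse = ""))
#' top_k_fraction(p, 6)
#' @export
top_k_fraction <- function(profile, k) {
  stopifnot(inherits(profile, "composition_profile"),
            k >= 1, k <= 20, k == round(k))
  ord <- order(-profile$frequencies, names(profile$frequencies))
  top <- ord[seq_len(k)]
  list(percent = sum(profile$frequencies[top]),
       residues = names(profile$frequencies)[top])
}

#' Fraction of sense codons encoding a residue set
#'
#' The baseline against which composition bias is judged: the percentage of
#' the 61 sense codons of the standard genetic code that encode any residue
#' in `residues`. The six most abundant long-exon residues
#' (Ser, Glu, Thr, Asp, Lys, Pro) are encoded by 20/61 = 32.8% of sense
#' codons.
#'
#' @param residues character vector of one-letter residue codes (a set).
#' @return percentage in 0-100; 0 for an empty set.
#' @examples
#' codon_fraction(c("S", "E", "T", "D", "K", "P"))  # 32.8
#' @export
codon_fraction <- function(residues) {
  residues <- unique(toupper(residues))
  if (!length(residues)) return(0)
  bad <- setdiff(residues, AA_ALPHABET)
  if (length(bad))
    stop("not standard residues: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tab <- sense_codon_table()
  100 * sum(tab[residues]) / sum(tab)
}

#' Long-exon vs core fold enrichment per residue
#'
#' Elementwise ratio of the averaged long-exon composition to the averaged
#' core composition. Residues with zero core frequency are flagged
#' (`NA` fold) rather than reported as infinite.
#'
#' @param long_avg,core_avg averaged `composition_profile`s.
#' @param fold_threshold residues whose fold exceeds this are listed in
#'   `enriched` (default 2).
#' @return list of class `enrichment_profile`: `fold` (named 20-vector),
#'   `undefined` (residue codes with zero core frequency), `enriched`.
#' @export
fold_enrichment <- function(long_avg, core_avg, fold_threshold = 2) {
  stopifnot(inherits(long_avg, "composition_profile"),
            inherits(core_avg, "composition_profile"))
  core <- core_avg$frequencies
  fold <- long_avg$frequencies / core
  undefined <- names(fold)[core == 0]
  fold[core == 0] <- NA_real_
  out <- list(fold = fold, undefined = undefined,
              enriched = names(fold)[!is.na(fold) & fold > fold_threshold],
              fold_threshold = fold_threshold)
  class(out) <- "enrichment_profile"
  out
}

#' @export
print.enrichment_profile <- function(x, digits = 2, ...) {
  cat("long-exon vs core fold enrichment\n")
  print(round(sort(x$fold, decreasing = TRUE, na.last = TRUE), digits))
  if (length(x$enriched))
    cat(sprintf("  > %.1f-fold enriched: %s\n", x$fold_threshold,
                paste(x$enriched, collapse = ", ")))
  if (length(x$undefined))
    cat("  undefined (zero core frequency):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Residues-by-sequences composition matrix
#'
#' Heatmap-ready matrix of per-sequence percent compositions with residues
#' ordered by ascending mean frequency (ties alphabetical), the layout used
#' to display composition bias across a sequence set.
#'
#' @param profiles list of `composition_profile`s.
#' @return numeric matrix, rows = sequences, columns = residues.
#' @export
composition_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "composition_profile")))
  mat <- t(vapply(profiles, `[[`, numeric(20), "frequencies"))
  colnames(mat) <- AA_ALPHABET
  nm <- names(profiles)
  rownames(mat) <- if (!is.null(nm)) nm else paste0("seq_", seq_len(nrow(mat)))
  ord <- order(colMeans(mat), colnames(mat))
  mat[, ord, drop = FALSE]
}
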