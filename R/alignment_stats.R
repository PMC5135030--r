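## Conservation statistics on a provided multiple sequence alignment.

## Accept a named character vector of equal-length aligned sequences, an
## AAMultipleAlignment, or an AAStringSet; return a named character vector.
#' @noRd
as_msa <- function(msa) {
  if (methods::is(msa, "AAMultipleAlignment") ||
      methods::is(msa, "DNAMultipleAlignment"))
    msa <- as.character(methods::slot(msa, "unmasked"))
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (!is.character(msa) || length(msa) < 2L)
    stop("msa must contain at least 2 aligned sequences", call. = FALSE)
  if (is.null(names(msa))) names(msa) <- paste0("seq_", seq_along(msa))
  if (anyDuplicated(names(msa)))
    stop("msa row ids must be unique", call. = FALSE)
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must have equal lengths", call. = FALSE)
  toupper(msa)
}

#' @noRd
msa_matrix <- function(msa) {
  msa <- as_msa(msa)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat[mat == "."] <- "-"
  mat
}

#' Column conservation counts for a multiple alignment
#'
#' For each alignment column, `m` is the size of the largest class of rows
#' sharing an identical residue (gaps never count as matches, so an all-gap
#' column has `m = 0`). The histogram over `m` gives the usual
#' "identical in all 4" / "identical in 3 of 4" style counts.
#'
#' @param msa named character vector of equal-length aligned sequences (or
#'   an `AAMultipleAlignment`/`AAStringSet`).
#' @return list of class `column_identity_counts`: `counts` (named vector,
#'   columns per `m` = 0..n_rows), `percent` (same, as percent of columns),
#'   `n_rows`, `n_columns`.
#' @export
column_identity_counts <- function(msa) {
  mat <- msa_matrix(msa)
  n_rows <- nrow(mat)
  m <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) 0L else max(table(col))
  })
  counts <- table(factor(m, levels = 0:n_rows))
  out <- list(counts = counts, percent = 100 * counts / ncol(mat),
              n_rows = n_rows, n_columns = ncol(mat))
  class(out) <- "column_identity_counts"
  out
}

#' @export
print.column_identity_counts <- function(x, ...) {
  cat(sprintf("column conservation over %d columns x %d rows\n",
              x$n_columns, x$n_rows))
  for (m in rev(seq_len(x$n_rows))) {
    k <- as.character(m)
    if (x$counts[k] > 0)
      cat(sprintf("  identical in %d of %d: %d columns (%.0f%%)\n",
                  m, x$n_rows, x$counts[k], x$percent[k]))
  }
  invisible(x)
}

#' Pairwise percent identity matrix from a multiple alignment
#'
#' Identity for each row pair computed over columns where neither row has a
#' gap (the denominator that reproduces core-domain identity figures);
#' an all-columns denominator is available. Pairs with zero gap-free columns
#' are reported as `NA` with a warning.
#'
#' @param msa as in [column_identity_counts()].
#' @param denominator `"gap_free"` (default) or `"all_cols"`.
#' @return symmetric numeric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
pairwise_identity_matrix <- function(msa,
                                     denominator = c("gap_free",
                                                     "all_cols")) {
  denominator <- match.arg(denominator)
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  out <- matrix(100, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      n_match <- sum(mat[i, both] == mat[j, both])
      denom <- if (denominator == "gap_free") sum(both) else ncol(mat)
      if (denom == 0) {
        warning("rows ", rownames(mat)[i], " and ", rownames(mat)[j],
                " share no gap-free columns; identity undefined",
                call. = FALSE)
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- 100 * n_match / denom
      }
    }
  }
  out
}
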