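#' Construct an annotated ankyrin locus
#'
#' Bundles the exon structure of an ankyrin gene prediction with the mapping
#' from conserved domains to exons. The UPA mapping anchors the long-exon
#' search window; the death-domain (DD) mapping, when present, classifies
#' candidate exon position. The DD mapping may be absent (e.g. lancelet
#' ankyrin, where no DD could be identified).
#'
#' @param contig_id contig the locus lies on.
#' @param strand `"+"` or `"-"` (transcription direction on the contig).
#' @param exons two-column matrix or data frame of 0-based half-open
#'   `(start, end)` nt intervals in transcription order, non-overlapping.
#' @param domain_exon_map named list mapping domain labels (`ANK_REPEATS`,
#'   `ZU5a`, `ZU5b`, `UPA`, `DD`) to integer vectors of exon indices; `UPA`
#'   is required.
#' @param downstream_gene_start nt offset of the adjacent downstream gene,
#'   or `NULL` to use the contig end.
#' @return list of class `locus_annotation`.
#' @export
locus_annotation <- function(contig_id, strand, exons, domain_exon_map,
                             downstream_gene_start = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exon intervals must satisfy start < end", call. = FALSE)
  ## transcription order: ascending starts on +, descending on -
  ord <- order(exons[, "start"], decreasing = (strand == "-"))
  if (!identical(ord, seq_len(nrow(exons))))
    stop("exons must be given in transcription order", call. = FALSE)
  genomic <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(genomic) > 1 &&
      any(genomic[-1, "start"] < genomic[-nrow(genomic), "end"]))
    stop("exons must be non-overlapping", call. = FALSE)
  if (is.null(domain_exon_map$UPA))
    stop("domain_exon_map must map UPA to at least one exon", call. = FALSE)
  for (d in names(domain_exon_map)) {
    idx <- domain_exon_map[[d]]
    if (any(idx < 1L | idx > nrow(exons)))
      stop("domain ", d, " maps to non-existent exons", call. = FALSE)
  }
  out <- list(contig_id = contig_id, strand = strand, exons = exons,
              domain_exon_map = domain_exon_map,
              downstream_gene_start = downstream_gene_start)
  class(out) <- "locus_annotation"
  out
}

#' @export
print.locus_annotation <- function(x, ...) {
  cat(sprintf("ankyrin locus on %s (%s): %d exons, domains: %s\n",
              x$contig_id, x$strand, nrow(x$exons),
              paste(names(x$domain_exon_map), collapse = ", ")))
  invisible(x)
}

#' Scan an ankyrin locus for candidate long exons
#'
#' Searches the genomic window downstream of the UPA domain — from the 3' end
#' of the last UPA-mapped exon to the start of the adjacent downstream gene
#' (or the contig end) — for large stop-free ORFs on the locus strand.
#' ORFs longer than `long_exon_min_nt` are flagged as passing the giant-exon
#' threshold; if no ORF exceeds `absence_min_nt` the locus receives an
#' absence certificate (the criterion used to conclude that cnidarian
#' ankyrins cannot encode giant isoforms). Each call is classified as lying
#' upstream or downstream of the death domain by comparing its midpoint to
#' the DD-mapped exon span (`DD_absent` when no DD is mapped). Calls
#' overlapping annotated exons of the input prediction are discarded.
#'
#' @param genome named character vector of contigs (or `DNAStringSet`).
#' @param locus a [locus_annotation()].
#' @param long_exon_min_nt ORFs longer than this are candidate giant exons
#'   (default 3000, the "> 3 kb" convention).
#' @param absence_min_nt absence is certified when no ORF exceeds this
#'   (default 1000, the "no ORFs > 1 kb" criterion).
#' @return list of class `long_exon_scan` with elements `calls` (data frame:
#'   `start`, `end`, `length_nt`, `position_vs_DD`, `passes_giant_threshold`),
#'   `search_window` (0-based half-open), `absence` (logical), `locus`.
#' @export
scan_locus <- function(genome, locus, long_exon_min_nt = 3000,
                       absence_min_nt = 1000) {
  genome <- as_genome(genome)
  if (!inherits(locus, "locus_annotation"))
    stop("locus must be a locus_annotation", call. = FALSE)
  if (!locus$contig_id %in% names(genome))
    stop("locus contig not present in genome", call. = FALSE)
  contig <- genome[[locus$contig_id]]
  clen <- nchar(contig)

  upa <- locus$exons[locus$domain_exon_map$UPA, , drop = FALSE]
  if (locus$strand == "+") {
    win_start <- max(upa[, "end"])
    win_end <- if (!is.null(locus$downstream_gene_start))
      locus$downstream_gene_start else clen
  } else {
    win_end <- min(upa[, "start"])
    win_start <- if (!is.null(locus$downstream_gene_start))
      locus$downstream_gene_start else 0L
  }
  win_start <- max(0L, win_start)
  win_end <- min(clen, win_end)

  empty_calls <- data.frame(start = integer(), end = integer(),
                            length_nt = integer(),
                            position_vs_DD = character(),
                            passes_giant_threshold = logical(),
                            stringsAsFactors = FALSE)
  if (win_end <= win_start) {
    out <- list(calls = empty_calls, search_window = c(win_start, win_end),
                absence = TRUE, locus = locus)
    class(out) <- "long_exon_scan"
    return(out)
  }

  window_seq <- substr(contig, win_start + 1L, win_end)
  orfs <- find_orfs(stats::setNames(window_seq, locus$contig_id),
                    min_orf_nt = 300)
  orfs <- orfs[orfs$strand == locus$strand, , drop = FALSE]
  orfs$start <- orfs$start + win_start
  orfs$end <- orfs$end + win_start

  ## drop calls overlapping annotated coding exons of the prediction
  if (nrow(orfs)) {
    overlaps_exon <- vapply(seq_len(nrow(orfs)), function(i) {
      any(orfs$start[i] < locus$exons[, "end"] &
            orfs$end[i] > locus$exons[, "start"])
    }, logical(1))
    orfs <- orfs[!overlaps_exon, , drop = FALSE]
  }

  absence <- !nrow(orfs) || max(orfs$length_nt) <= absence_min_nt
  orfs <- orfs[orfs$length_nt > absence_min_nt, , drop = FALSE]

  if (!nrow(orfs)) {
    calls <- empty_calls
  } else {
    pos <- vapply(seq_len(nrow(orfs)), function(i)
      classify_position(orfs$start[i], orfs$end[i], locus), character(1))
    calls <- data.frame(start = orfs$start, end = orfs$end,
                        length_nt = orfs$length_nt, position_vs_DD = pos,
                        passes_giant_threshold =
                          orfs$length_nt > long_exon_min_nt,
                        stringsAsFactors = FALSE)
    calls <- calls[order(calls$start), , drop = FALSE]
    rownames(calls) <- NULL
  }
  out <- list(calls = calls, search_window = c(win_start, win_end),
              absence = absence, locus = locus)
  class(out) <- "long_exon_scan"
  out
}

## upstream/downstream is in the transcription sense: on "+" upstream of DD
## means a smaller coordinate than the DD exon span; mirrored on "-".
#' @noRd
classify_position <- function(start, end, locus) {
  dd_idx <- locus$domain_exon_map$DD
  if (is.null(dd_idx)) return("DD_absent")
  dd <- locus$exons[dd_idx, , drop = FALSE]
  dd_lo <- min(dd[, "start"])
  dd_hi <- max(dd[, "end"])
  mid <- (start + end) / 2
  if (mid >= dd_lo && mid < dd_hi) {
    warning("candidate long exon overlaps the DD exon span; ",
            "classified upstream_of_DD", call. = FALSE)
    return("upstream_of_DD")
  }
  before <- mid < dd_lo
  if (locus$strand == "+") {
    if (before) "upstream_of_DD" else "downstream_of_DD"
  } else {
    if (before) "downstream_of_DD" else "upstream_of_DD"
  }
}

#' @export
print.long_exon_scan <- function(x, ...) {
  cat(sprintf("long-exon scan of %s (%s), window %d-%d nt\n",
              x$locus$contig_id, x$locus$strand,
              x$search_window[1], x$search_window[2]))
  if (x$absence) {
    cat("  no ORF above the absence threshold: locus cannot encode a giant isoform\n")
  } else {
    n_pass <- sum(x$calls$passes_giant_threshold)
    cat(sprintf("  %d candidate ORF(s), %d passing the giant-exon threshold (%s)\n",
                nrow(x$calls), n_pass, classify_exon_count(x)))
    print(x$calls)
  }
  invisible(x)
}

#' Classify how many long exons a locus carries
#'
#' @param calls a `long_exon_scan` from [scan_locus()], or its `calls` data
#'   frame.
#' @return `"none"`, `"single"`, or `"tandem"` (two or more passing calls in
#'   the same search window, as seen for the fly Ank2 L/XL exon pair).
#' @export
classify_exon_count <- function(calls) {
  if (inherits(calls, "long_exon_scan")) calls <- calls$calls
  n <- sum(calls$passes_giant_threshold)
  if (n == 0L) "none" else if (n == 1L) "single" else "tandem"
}
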