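## File-format frontends. Sequence formats go through Biostrings, GFF3
## through rtracklayer; internal representations are plain named character
## vectors and data frames with 0-based half-open coordinates.

#' Read a (multi-contig) genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  out <- as.character(Biostrings::readAAStringSet(path))
  ## FASTA headers often carry descriptions; keep the first token as the id
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Read an aligned protein FASTA as an MSA
#'
#' @param path aligned FASTA file (equal-length rows, `-` gaps).
#' @return named character vector of aligned rows.
#' @export
read_msa_fasta <- function(path) {
  as_msa(read_protein_fasta(path))
}

#' Write an ORF set as BED6
#'
#' Name is `contig:frame:strand`, score is `length_nt`; coordinates are
#' already 0-based half-open as BED requires.
#'
#' @param orfs an `orf_set` from [find_orfs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orf_bed <- function(orfs, path) {
  bed <- data.frame(chrom = orfs$contig_id, start = orfs$start,
                    end = orfs$end,
                    name = paste(orfs$contig_id, orfs$frame, orfs$strand,
                                 sep = ":"),
                    score = orfs$length_nt, strand = orfs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annotated ankyrin locus from GFF3
#'
#' Expected dialect: features of type `exon` on one seqid and strand, in
#' genomic order, each optionally carrying a `domain` attribute naming one
#' of `ANK_REPEATS`, `ZU5a`, `ZU5b`, `UPA`, `DD` (an exon spanning several
#' domains may list them comma-separated); an optional feature of type
#' `gene` with attribute `role=downstream` marks the adjacent downstream
#' gene. GFF3 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return a [locus_annotation()].
#' @export
read_locus_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  exon_rows <- meta[meta$type == "exon", , drop = FALSE]
  if (!nrow(exon_rows)) stop("no exon features in ", path, call. = FALSE)
  if (length(unique(as.character(exon_rows$seqnames))) != 1L)
    stop("exons span multiple seqids", call. = FALSE)
  strand <- unique(as.character(exon_rows$strand))
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("exons must share one explicit strand", call. = FALSE)
  exon_rows <- exon_rows[order(exon_rows$start,
                               decreasing = (strand == "-")), , drop = FALSE]
  exons <- cbind(start = exon_rows$start - 1L, end = exon_rows$end)

  domain_map <- list()
  if (!is.null(exon_rows$domain)) {
    for (i in seq_len(nrow(exon_rows))) {
      d <- exon_rows$domain[i]
      if (is.na(d) || !nzchar(d)) next
      for (lab in strsplit(d, ",", fixed = TRUE)[[1L]])
        domain_map[[trimws(lab)]] <- c(domain_map[[trimws(lab)]], i)
    }
  }

  dgs <- NULL
  gene_rows <- meta[meta$type == "gene", , drop = FALSE]
  if (!is.null(gene_rows$role))
    gene_rows <- gene_rows[!is.na(gene_rows$role) &
                             gene_rows$role == "downstream", , drop = FALSE]
  if (nrow(gene_rows)) {
    ## nearest edge of the downstream gene on the transcription axis
    dgs <- if (strand == "+") min(gene_rows$start) - 1L else
      max(gene_rows$end)
  }
  locus_annotation(unique(as.character(exon_rows$seqnames)), strand, exons,
                   domain_map, dgs)
}

#' Write a simulated or curated locus as GFF3
#'
#' Inverse of [read_locus_gff3()] (same dialect).
#'
#' @param locus a [locus_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(locus, path) {
  stopifnot(inherits(locus, "locus_annotation"))
  lines <- "##gff-version 3"
  dom_for <- function(i) {
    labs <- names(locus$domain_exon_map)[vapply(locus$domain_exon_map,
                                                function(v) i %in% v,
                                                logical(1))]
    if (length(labs)) paste0(";domain=", paste(labs, collapse = ",")) else ""
  }
  for (i in seq_len(nrow(locus$exons))) {
    lines <- c(lines, paste(locus$contig_id, "giantexon", "exon",
                            locus$exons[i, "start"] + 1L,
                            locus$exons[i, "end"], ".", locus$strand, ".",
                            paste0("ID=exon", i, dom_for(i)), sep = "\t"))
  }
  if (!is.null(locus$downstream_gene_start)) {
    s <- locus$downstream_gene_start
    coords <- if (locus$strand == "+") c(s + 1L, s + 1L) else c(s, s)
    lines <- c(lines, paste(locus$contig_id, "giantexon", "gene",
                            coords[1], coords[2], ".", locus$strand, ".",
                            "ID=downstream_gene;role=downstream", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FRAP trace from CSV
#'
#' Expected columns: `time_s`, `bleach`, `reference`.
#'
#' @param path CSV file.
#' @param bleach_time_s bleach time in seconds.
#' @return a [frap_trace()].
#' @export
read_frap_csv <- function(path, bleach_time_s) {
  df <- utils::read.csv(path)
  need <- c("time_s", "bleach", "reference")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  frap_trace(df$time_s, df$bleach, df$reference, bleach_time_s)
}

#' Read an axon intensity profile from CSV
#'
#' Expected columns: `distance_um`, `intensity`.
#'
#' @param path CSV file.
#' @return a normalized profile from [normalize_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("distance_um", "intensity")
  if (!all(need %in% names(df)))
    stop("profile CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  normalize_profile(df$distance_um, df$intensity)
}
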