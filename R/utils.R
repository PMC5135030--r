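## Internal helpers shared across modules: sequence validation, genetic-code
## tables, and seeded RNG streams for the generators.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "J", "O", "*")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1L]]), DNA_ALPHABET)
  if (length(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sequence
}

#' @noRd
check_protein <- function(sequence, what = "protein", allow_ambiguous = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  allowed <- if (allow_ambiguous) c(AA_ALPHABET, AA_AMBIGUOUS) else AA_ALPHABET
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1L]]), allowed)
  if (length(bad))
    stop(what, " contains non-residue characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sequence
}

## Accept a plain named character vector, a Biostrings *StringSet, or a single
## string; always return a named character vector of contigs.
#' @noRd
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- as.character(genome)
  if (!is.character(genome))
    stop("genome must be a (named) character vector or DNAStringSet",
         call. = FALSE)
  if (is.null(names(genome)))
    names(genome) <- if (length(genome) == 1L) "contig_1" else
      paste0("contig_", seq_along(genome))
  if (anyDuplicated(names(genome)))
    stop("contig ids must be unique", call. = FALSE)
  vapply(genome, check_dna, character(1), what = "genome sequence")
}

#' @noRd
revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1L]]), collapse = ""))
}

## Sense-codon counts per residue from the standard genetic code (61 codons).
#' @noRd
sense_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  table(factor(gc[gc != "*"], levels = AA_ALPHABET))
}

## --- seeded RNG streams -----------------------------------------------------
## Each generator draws from its own stream derived from (seed, kind) so that
## adding generators never perturbs existing fixtures, and the caller's RNG
## state is untouched.

#' @noRd
derive_seed <- function(seed, kind) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  h <- sum(utf8ToInt(kind) * seq_len(nchar(kind)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' @noRd
with_gen_seed <- function(seed, kind, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, kind))
  force(code)
}
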