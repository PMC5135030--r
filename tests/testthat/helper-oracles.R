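## Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Naive six-frame ORF oracle built on Biostrings translation: translate
## each frame of each strand, take maximal runs free of stops (and of the X
## produced by N-containing codons), and map back to forward coordinates.
oracle_find_orfs <- function(genome, min_orf_nt = 300, strict = TRUE) {
  res <- list()
  for (cid in names(genome)) {
    fwd <- genome[[cid]]
    len <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      for (frame in 0:2) {
        n_codons <- (nchar(s) - frame) %/% 3
        if (n_codons < 1) next
        sub <- substr(s, frame + 1, frame + 3 * n_codons)
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                 if.fuzzy.codon = "X"))
        runs <- gregexpr("[^*X]+", aa)[[1]]
        if (runs[1] == -1) next
        for (k in seq_along(runs)) {
          aa_start <- runs[k]
          aa_len <- attr(runs, "match.length")[k]
          start <- frame + 3 * (aa_start - 1)
          end <- start + 3 * aa_len
          length_nt <- 3 * aa_len
          keep <- if (strict) length_nt > min_orf_nt else
            length_nt >= min_orf_nt
          if (!keep) next
          if (strand == "-") {
            tmp <- len - end
            end <- len - start
            start <- tmp
          }
          res[[length(res) + 1]] <- data.frame(
            contig_id = cid, start = start, end = end, strand = strand,
            frame = frame, length_nt = length_nt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), length_nt = integer()))
  out <- do.call(rbind, res)
  out <- out[order(out$contig_id, out$start, out$end, out$strand, out$frame), ]
  rownames(out) <- NULL
  out
}

orf_key <- function(orfs) {
  sort(paste(orfs$contig_id, orfs$start, orfs$end, orfs$strand, orfs$frame,
             sep = ":"))
}

## Brute-force simple-repeat masking oracle: for every position and motif
## length, test directly whether a tandem run of that motif covering the
## position spans at least min_run_nt.
oracle_repeat_mask <- function(sequence, motif_max_nt = 6, min_run_nt = 50) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  len <- length(chars)
  mask <- logical(len)
  for (m in seq_len(motif_max_nt)) {
    i <- 1
    while (i + m <= len) {
      j <- i
      while (j + m <= len && chars[j + m] == chars[j]) j <- j + 1
      run_span <- j + m - i
      if (run_span >= min_run_nt && j > i) mask[i:(j + m - 1)] <- TRUE
      i <- if (j > i) j else i + 1
    }
  }
  mask
}

## Build a pairwise_alignment object directly from two aligned strings.
make_alignment <- function(aligned_a, aligned_b, setting_id = "manual") {
  out <- list(aligned_a = aligned_a, aligned_b = aligned_b,
              score = NA_real_, setting_id = setting_id)
  class(out) <- "pairwise_alignment"
  out
}

## Run-length-encoding oracle for identity runs of an alignment.
oracle_run_histogram <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  match <- ca == cb & ca != "-"
  runs <- integer(0)
  cur <- 0
  for (m in match) {
    if (m) cur <- cur + 1
    else if (cur > 0) { runs <- c(runs, cur); cur <- 0 }
  }
  if (cur > 0) runs <- c(runs, cur)
  runs
}
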