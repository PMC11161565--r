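#' Locus consensus sequence sets
#'
#' Per-locus, per-individual consensus sequences (alphabet A, C, G, T,
#' N), the raw material for pseudoreference construction and
#' mapping-affinity scoring. All sequences of one locus must have equal
#' length (the generator emits SNP-only variation; indels are out of
#' model).
#'
#' @param locus_id,individual,seq parallel vectors.
#' @return a `locus_seqset`: data.table with those three columns.
#' @export
locus_seqset <- function(locus_id, individual, seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) && !all(grepl("^[ACGTN]+$", seq)))
    stop("sequences must use alphabet {A,C,G,T,N}")
  dt <- data.table(locus_id = as.character(locus_id),
                   individual = as.character(individual), seq = seq)
  if (anyDuplicated(dt[, c("locus_id", "individual")]))
    stop("duplicate (locus_id, individual) entry")
  len_ok <- dt[, length(unique(nchar(seq))) == 1L, by = "locus_id"]
  if (!all(len_ok$V1))
    stop("unequal sequence lengths within locus: ",
         paste(len_ok$locus_id[!len_ok$V1], collapse = ", "))
  structure(dt, class = c("locus_seqset", "data.table", "data.frame"))
}

#' Read locus sequences from FASTA
#'
#' Header convention: `>locusID|individualID`.
#'
#' @param path FASTA file.
#' @return a [locus_seqset()].
#' @export
read_locus_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  parts <- strsplit(nm, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("FASTA headers must be 'locusID|individualID'; bad: ",
                     paste(head(nm[bad], 3), collapse = ", "))
  locus_seqset(
    vapply(parts, `[`, character(1), 1L),
    vapply(parts, `[`, character(1), 2L),
    as.character(ss)
  )
}

#' @rdname read_locus_fasta
#' @param seqs a [locus_seqset()].
#' @export
write_locus_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", seqs$locus_id, "|", seqs$individual, "\n", seqs$seq),
             con)
  invisible(path)
}
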