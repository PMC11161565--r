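#' Build a per-taxon pseudoreference
#'
#' Collects the per-individual locus consensus sequences of one
#' ancestral taxon verbatim — the "mixed" reference: no merging, every
#' contributing individual's consensus is retained as a separate entry
#' (duplicates included), so a target matches the taxon if it is close
#' to *any* member of it. N bases are preserved.
#'
#' @param seqs a [locus_seqset()].
#' @param pops a [pop_map()].
#' @param taxon population label of the taxon.
#' @return a `pseudoreference`: list(`taxon`, `sequences`) where
#'   `sequences` is the taxon's subset of `seqs`.
#' @export
build_pseudoreference <- function(seqs, pops, taxon) {
  inds <- pop_individuals(pops, taxon)
  sub <- seqs[seqs$individual %in% inds, ]
  if (!nrow(sub)) stop("taxon ", taxon, " has no sequences")
  structure(list(taxon = taxon, sequences = as.data.table(sub)),
            class = "pseudoreference")
}

# Hamming distance with N as wildcard; sequences must be equal length.
hamming_n <- function(x, y) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  if (length(cx) != length(cy)) stop("unequal sequence lengths")
  sum(cx != cy & cx != "N" & cy != "N")
}

#' Mapping affinity of individuals to pseudoreferences
#'
#' Desk-scale stand-in for read mapping against per-taxon references: a
#' target's locus counts as mapped to a taxon iff the minimum Hamming
#' distance (N matches anything) between the target's consensus and any
#' of the taxon's entries for that locus is at most `max_mismatch`
#' (default 1, mirroring a maximum-one-difference aligner setting).
#' `raw` is the fraction of the target's non-missing loci mapped; to
#' remove inter-individual data-quality differences, the mean across
#' taxa within each individual is subtracted (`centered`; row means are
#' 0 by construction).
#'
#' @param seqs a [locus_seqset()] holding the targets' sequences.
#' @param refs list of [build_pseudoreference()] objects.
#' @param targets character vector of target individual ids.
#' @param max_mismatch non-negative integer mismatch budget.
#' @return an `affinity_result`: data.table `individual`, `taxon`,
#'   `raw`, `centered`. Targets with no loci get `NA` (logged).
#' @export
mapping_affinity <- function(seqs, refs, targets, max_mismatch = 1L) {
  stopifnot(max_mismatch >= 0)
  taxa <- vapply(refs, `[[`, character(1), "taxon")
  # pre-split reference sequences per locus per taxon into char matrices
  ref_mats <- lapply(refs, function(r) {
    sq <- r$sequences
    spl <- split(sq$seq, sq$locus_id)
    lapply(spl, function(v)
      matrix(unlist(strsplit(v, "")), ncol = length(v)))
  })
  names(ref_mats) <- taxa
  rows <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    mine <- seqs[seqs$individual == tg, ]
    if (!nrow(mine)) {
      pa_log("no loci for target ", tg, " -> NA affinity", level = "WARN")
      rows[[ti]] <- data.table(individual = tg, taxon = taxa,
                               raw = NA_real_, centered = NA_real_)
      next
    }
    tchars <- lapply(strsplit(mine$seq, ""), identity)
    mapped <- stats::setNames(numeric(length(taxa)), taxa)
    for (k in seq_along(taxa)) {
      rm_k <- ref_mats[[k]]
      hit <- 0L
      for (li in seq_len(nrow(mine))) {
        m <- rm_k[[mine$locus_id[li]]]
        if (is.null(m)) next
        tv <- tchars[[li]]
        if (nrow(m) != length(tv)) stop("unequal sequence lengths in locus ",
                                        mine$locus_id[li])
        dists <- colSums(m != tv & m != "N" & tv != "N")
        if (min(dists) <= max_mismatch) hit <- hit + 1L
      }
      mapped[k] <- hit / nrow(mine)
    }
    rows[[ti]] <- data.table(individual = tg, taxon = taxa,
                             raw = unname(mapped),
                             centered = unname(mapped - mean(mapped)))
  }
  out <- rbindlist(rows)
  structure(out, class = c("affinity_result", class(out)))
}

#' @rdname mapping_affinity
#' @param x an `affinity_result`.
#' @param path output TSV path.
#' @export
write_affinity <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
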