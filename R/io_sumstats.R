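#' Read a Stacks-style per-site population summary table
#'
#' Parses the tab-separated per-site, per-population summary dialect
#' modeled on the `populations.sumstats.tsv` file of the Stacks
#' `populations` module: one row per (variant site, population) with the
#' major/minor nucleotides, the major-allele frequency, observed
#' heterozygosity and a private-allele flag. Comment lines starting with
#' `#` that are not the header are skipped; the header row itself may
#' carry a leading `# `. Windows line endings are tolerated. Unknown
#' columns are preserved.
#'
#' @param path path to the TSV.
#' @return a data.table with canonical columns `locus_id`, `col`,
#'   `pop_id`, `p_nuc`, `q_nuc`, `p`, `obs_het`, `private` (plus any
#'   extra columns from the file).
#' @export
read_sumstats_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr_i <- which(!startsWith(lines, "#") |
                   grepl("Locus", lines, fixed = TRUE))[1]
  if (is.na(hdr_i)) stop("sumstats file has no header row")
  lines[hdr_i] <- sub("^#\\s*", "", lines[hdr_i])
  dt <- fread(text = paste(lines[hdr_i:length(lines)], collapse = "\n"),
              sep = "\t", header = TRUE)
  canon <- c("Locus ID" = "locus_id", "Col" = "col", "Pop ID" = "pop_id",
             "P Nuc" = "p_nuc", "Q Nuc" = "q_nuc", "P" = "p",
             "Obs Het" = "obs_het", "Private" = "private")
  found <- names(dt)
  for (nm in names(canon)) {
    if (nm %in% found) setnames(dt, nm, canon[[nm]])
  }
  need <- unname(canon)
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("sumstats schema error; expected columns [",
         paste(names(canon), collapse = ", "), "] but missing [",
         paste(names(canon)[canon %in% miss], collapse = ", "), "]")
  dt$locus_id <- as.character(dt$locus_id)
  dt$pop_id <- as.character(dt$pop_id)
  dt$col <- as.integer(dt$col)
  dt$p <- as.numeric(dt$p)
  dt$obs_het <- as.numeric(dt$obs_het)
  dt[]
}

#' Write a per-site population summary table
#'
#' Inverse of [read_sumstats_tsv()]; emits the Stacks-style header names.
#'
#' @param ss data.table as returned by [read_sumstats_tsv()] or
#'   [sumstats_from_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats_tsv <- function(ss, path) {
  out <- as.data.table(ss)
  canon <- c(locus_id = "Locus ID", col = "Col", pop_id = "Pop ID",
             p_nuc = "P Nuc", q_nuc = "Q Nuc", p = "P",
             obs_het = "Obs Het", private = "Private")
  for (nm in names(canon)) if (nm %in% names(out)) setnames(out, nm, canon[[nm]])
  fwrite(out, path, sep = "\t", quote = FALSE, na = "-")
  invisible(path)
}

#' Summarize a genotype table per site and population
#'
#' Computes the per-site, per-population rows of the sumstats dialect
#' from a genotype table: major (`p_nuc`) and minor (`q_nuc`) nucleotide
#' within the population, major-allele frequency `p` (allele copies from
#' pseudo-diploid calls: homozygote two, heterozygote one of each),
#' observed heterozygosity, and whether an allele at the site is private
#' to the population against all others in the map.
#'
#' @param gt a [genotype_table()].
#' @param pops a [pop_map()] covering the table.
#' @return a data.table in the canonical sumstats layout.
#' @export
sumstats_from_table <- function(gt, pops) {
  check_popmap(gt, pops)
  labels <- unique(pops$population)
  pres_by_pop <- lapply(labels, function(p)
    allele_presence(gt, intersect(pop_individuals(pops, p), gt$individuals)))
  names(pres_by_pop) <- labels
  sp <- split_calls(gt)
  rows <- vector("list", length(labels))
  for (pi in seq_along(labels)) {
    p <- labels[pi]
    inds <- intersect(pop_individuals(pops, p), gt$individuals)
    a1 <- sp$a1[inds, , drop = FALSE]
    a2 <- sp$a2[inds, , drop = FALSE]
    cnt <- sapply(NUCS, function(a)
      colSums(a1 == a, na.rm = TRUE) + colSums(a2 == a, na.rm = TRUE))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, NUCS))
    tot <- rowSums(cnt)
    major <- NUCS[max.col(cnt, ties.method = "first")]
    cnt2 <- cnt
    cnt2[cbind(seq_len(nrow(cnt)), match(major, NUCS))] <- -1L
    minor_n <- apply(cnt2, 1L, max)
    minor <- ifelse(minor_n > 0, NUCS[max.col(cnt2, ties.method = "first")], "-")
    pfreq <- ifelse(tot > 0, cnt[cbind(seq_len(nrow(cnt)), match(major, NUCS))] / tot, NA_real_)
    nm <- colSums(!is.na(a1))
    het <- colSums(a1 != a2, na.rm = TRUE)
    # private: any allele present here and in no other population
    others <- Reduce(`|`, pres_by_pop[setdiff(labels, p)],
                     matrix(FALSE, 4L, ncol(a1)))
    priv <- colSums(pres_by_pop[[p]] & !others) > 0
    rows[[pi]] <- data.table(
      locus_id = gt$sites$locus_id, col = gt$sites$column,
      pop_id = p, p_nuc = ifelse(tot > 0, major, "-"),
      q_nuc = minor, p = round(pfreq, 5),
      obs_het = round(ifelse(nm > 0, het / nm, NA_real_), 5),
      private = as.integer(priv)
    )
  }
  rbindlist(rows)
}
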