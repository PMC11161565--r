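#' Read a VCF into a genotype table
#'
#' Reads biallelic or multiallelic SNP records with diploid GT fields and
#' converts each genotype to a pseudo-diploid call (the set of distinct
#' called alleles); `./.` becomes missing. Non-SNP records (indels,
#' symbolic alleles) are skipped with a logged count.
#'
#' RAD loci are not standardized in VCF, so locus assignment is
#' configurable: if the file carries the `LOC` INFO key (as written by
#' [write_vcf()]) it is used, together with `COL` for the within-locus
#' column; otherwise sites are binned into pseudo-loci as
#' `chrom:floor(pos / bin_size)` with `column = pos - bin * bin_size`.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param bin_size locus bin width in bp when the file lacks `LOC`
#'   annotations (default 1000).
#' @return a [genotype_table()].
#' @export
read_vcf <- function(path, bin_size = 1000L) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  alt <- lapply(seq_along(altl), function(i) as.character(altl[[i]]))
  is_snp <- nchar(ref) == 1L & ref %in% NUCS &
    vapply(alt, function(a) length(a) == 0L ||
             all(nchar(a) == 1L & a %in% NUCS), logical(1))
  if (any(!is_snp))
    pa_log(sum(!is_snp), " non-SNP record(s) skipped")
  gtm <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtm)) stop("VCF has no GT field")
  info <- VariantAnnotation::info(vcf)

  idx <- which(is_snp)
  chrom <- as.character(GenomicRanges::seqnames(rr))[idx]
  pos <- GenomicRanges::start(rr)[idx]
  site_id <- rownames(gtm)[idx]
  if (is.null(site_id)) site_id <- paste0(chrom, ":", pos)
  if ("SID" %in% names(info)) {
    sid <- as.character(info$SID)[idx]
    site_id <- ifelse(is.na(sid), site_id, sid)
  }
  if ("LOC" %in% names(info) && !all(is.na(info$LOC))) {
    locus_id <- as.character(info$LOC)[idx]
    column <- if ("COL" %in% names(info)) as.integer(info$COL)[idx] else
      seq_along(idx) - 1L
  } else {
    bin <- floor(pos / bin_size)
    locus_id <- paste0(chrom, ":", bin)
    column <- as.integer(pos - bin * bin_size)
  }
  synthetic <- if ("SYNPOS" %in% names(info))
    as.logical(info$SYNPOS)[idx] else rep(FALSE, length(idx))
  chrom[synthetic] <- NA_character_
  pos_out <- pos
  pos_out[synthetic] <- NA_integer_

  samples <- colnames(gtm)
  alleles <- mapply(function(r, a) c(r, a), ref[idx], alt[idx],
                    SIMPLIFY = FALSE)
  # decode GT strings column-wise; diploid "i/j" (or phased "i|j")
  calls <- matrix(NA_character_, length(samples), length(idx),
                  dimnames = list(samples, site_id))
  gsub_miss <- function(x) ifelse(x %in% c("./.", ".", ".|."), NA, x)
  for (j in seq_along(idx)) {
    g <- gsub_miss(gtm[idx[j], ])
    sp <- strsplit(g, "[/|]")
    al <- alleles[[j]]
    a1 <- vapply(sp, function(v)
      if (length(v) < 1L || is.na(v[1]) || v[1] == ".") NA_character_ else
        al[as.integer(v[1]) + 1L], character(1))
    a2 <- vapply(sp, function(v)
      if (length(v) < 2L || is.na(v[2]) || v[2] == ".") NA_character_ else
        al[as.integer(v[2]) + 1L], character(1))
    a2 <- ifelse(is.na(a2) & !is.na(a1), a1, a2)  # haploid call -> hom
    calls[, j] <- canon_call(a1, a2)
  }
  genotype_table(
    samples,
    data.frame(site_id = site_id, locus_id = locus_id, column = column,
               chrom = chrom, pos = pos_out),
    calls
  )
}

#' Write a genotype table as VCF
#'
#' Emits a minimal VCF 4.2 with one SNP record per site and diploid GT
#' calls. Locus structure is preserved in the `LOC`/`COL` INFO keys and
#' the original site id in `SID`, so [read_vcf()] round-trips the table
#' exactly. Sites without genomic coordinates get synthetic ones (chrom =
#' locus id, pos = column + 1) flagged with `SYNPOS` so the reader can
#' restore the missing coordinates.
#'
#' REF is chosen as the alphabetically first allele observed at the site
#' (the table does not track reference state).
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  pres <- allele_presence(gt)
  sp <- split_calls(gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=patrace",
    "##INFO=<ID=LOC,Number=1,Type=String,Description=\"RAD locus id\">",
    "##INFO=<ID=COL,Number=1,Type=Integer,Description=\"Column offset within locus\">",
    "##INFO=<ID=SID,Number=1,Type=String,Description=\"Site id\">",
    "##INFO=<ID=SYNPOS,Number=0,Type=Flag,Description=\"CHROM/POS are synthetic placeholders\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$individuals), collapse = "\t")
  ), con)
  st <- gt$sites
  for (j in seq_len(nrow(st))) {
    obs <- NUCS[pres[, j]]
    if (length(obs) == 0L) obs <- "A"  # fully missing site: placeholder REF
    ref <- obs[1]
    alt <- if (length(obs) > 1L) paste(obs[-1], collapse = ",") else "."
    syn <- is.na(st$chrom[j])
    chrom <- if (syn) st$locus_id[j] else st$chrom[j]
    pos <- if (syn) st$column[j] + 1L else st$pos[j]
    info <- sprintf("LOC=%s;COL=%d;SID=%s%s", st$locus_id[j], st$column[j],
                    st$site_id[j], if (syn) ";SYNPOS" else "")
    idx <- setNames(seq_along(obs) - 1L, obs)
    a1 <- sp$a1[, j]; a2 <- sp$a2[, j]
    gtf <- ifelse(is.na(a1), "./.", paste0(idx[a1], "/", idx[a2]))
    writeLines(paste(c(chrom, pos, st$site_id[j], ref, alt, ".", "PASS",
                       info, "GT", gtf), collapse = "\t"), con)
  }
  invisible(path)
}
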