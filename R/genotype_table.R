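#' Genotype table of pseudo-diploid calls
#'
#' The central container of the package: an individuals-by-sites matrix of
#' unphased pseudo-diploid allele calls. A call is the *set* of distinct
#' alleles a diploid genotyper reported for an individual at a variant
#' site — at most two of A, C, G, T — encoded as `"A"` (one allele
#' observed), `"A/T"` (two, sorted alphabetically), or `NA` (missing).
#' Allele dosage is deliberately not represented: in polyploids genotyped
#' with a diploid caller the dosage is unknowable, and every downstream
#' statistic here uses presence/absence plus diploid genotype frequencies.
#'
#' Sites are grouped into loci (RAD loci); the site table carries the
#' locus id, the column offset of the site within its locus, and an
#' optional genomic coordinate (`chrom`/`pos`, present together or not at
#' all).
#'
#' @param individuals character vector of unique individual ids (row
#'   order of `calls`).
#' @param sites data.frame with columns `site_id` (unique), `locus_id`,
#'   `column` (non-negative integer offset within the locus), and
#'   optional `chrom`, `pos` (1-based). `(locus_id, column)` must be
#'   unique.
#' @param calls character matrix `length(individuals)` x `nrow(sites)`
#'   of canonical call strings (see Details); `NA` is missing.
#' @return an object of class `genotype_table` with elements
#'   `individuals`, `sites` (data.table) and `calls` (dimnames set to
#'   individual and site ids).
#' @export
#' @examples
#' gt <- genotype_table(
#'   individuals = c("S1", "S2"),
#'   sites = data.frame(site_id = "s1", locus_id = "L1", column = 0L),
#'   calls = matrix(c("A/T", "A"), nrow = 2, ncol = 1)
#' )
#' gt
genotype_table <- function(individuals, sites, calls) {
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  sites <- as.data.table(sites)
  for (col in c("site_id", "locus_id")) {
    if (!col %in% names(sites)) stop("sites must have column '", col, "'")
    sites[[col]] <- as.character(sites[[col]])
  }
  if (!"column" %in% names(sites)) stop("sites must have column 'column'")
  sites$column <- as.integer(sites$column)
  if (any(sites$column < 0L)) stop("site column offsets must be >= 0")
  if (!"chrom" %in% names(sites)) sites$chrom <- NA_character_
  if (!"pos" %in% names(sites)) sites$pos <- NA_integer_
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(is.na(sites$chrom) != is.na(sites$pos)))
    stop("chrom and pos must be present together")
  if (anyDuplicated(sites$site_id)) stop("site_id must be unique")
  if (anyDuplicated(sites[, c("locus_id", "column")]))
    stop("(locus_id, column) must be unique")
  calls <- as.matrix(calls)
  if (nrow(calls) != length(individuals) || ncol(calls) != nrow(sites))
    stop("calls must be |individuals| x |sites|")
  mode(calls) <- "character"
  bad <- calls[!is.na(calls)]
  het <- bad[nchar(bad) == 3L]
  if (length(bad) && (!all(grepl("^[ACGT](/[ACGT])?$", bad)) ||
                      any(substr(het, 1, 1) > substr(het, 3, 3))))
    stop("calls must look like 'A' or 'A/T' (sorted) or NA")
  dimnames(calls) <- list(individuals, sites$site_id)
  structure(
    list(individuals = individuals, sites = sites[], calls = calls),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d sites (%d loci), %.1f%% missing\n",
    length(x$individuals), nrow(x$sites),
    length(unique(x$sites$locus_id)), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

# Split the call matrix into two allele matrices (hom -> same allele in
# both). Used by every allele-presence computation.
split_calls <- function(gt) {
  calls <- gt$calls
  a1 <- sub("/.*$", "", calls)
  a2 <- sub("^.*/", "", calls)
  list(a1 = a1, a2 = a2)
}

# Per-site x allele presence indicator over a subset of individuals.
# Returns a 4 x n_sites logical matrix (rows A,C,G,T).
allele_presence <- function(gt, individuals = gt$individuals) {
  sp <- split_calls(gt)
  a1 <- sp$a1[individuals, , drop = FALSE]
  a2 <- sp$a2[individuals, , drop = FALSE]
  pres <- matrix(FALSE, 4L, ncol(a1), dimnames = list(NUCS, colnames(a1)))
  for (a in NUCS) {
    pres[a, ] <- colSums(a1 == a, na.rm = TRUE) + colSums(a2 == a, na.rm = TRUE) > 0
  }
  pres
}

#' Subset a genotype table
#'
#' @param gt a [genotype_table()].
#' @param individuals,site_ids ids to keep (default: all).
#' @return a `genotype_table`.
#' @export
subset_table <- function(gt, individuals = gt$individuals,
                         site_ids = gt$sites$site_id) {
  stopifnot(inherits(gt, "genotype_table"))
  keep <- gt$sites$site_id %in% site_ids
  genotype_table(
    individuals,
    gt$sites[keep, ],
    gt$calls[individuals, gt$sites$site_id[keep], drop = FALSE]
  )
}

#' Population map
#'
#' Assigns every individual to a population label and a role. Roles:
#' `ancestral` populations define the privacy universe for private-allele
#' catalogues; `derived` populations are tracing targets; a
#' `proxy_polyploid` population stands in for an extinct ancestor that
#' left no extant diploid samples (its alleles not found in any extant
#' ancestor are attributed to the ghost lineage).
#'
#' @param individual character vector of individual ids (unique).
#' @param population character vector of population labels.
#' @param role character vector, each one of `"ancestral"`, `"derived"`,
#'   `"proxy_polyploid"`.
#' @return a `pop_map`: data.table with those three columns.
#' @export
pop_map <- function(individual, population, role) {
  individual <- as.character(individual)
  population <- as.character(population)
  role <- as.character(role)
  stopifnot(length(individual) == length(population),
            length(individual) == length(role))
  if (anyDuplicated(individual))
    stop("duplicate individual in population map: ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  ok <- role %in% c("ancestral", "derived", "proxy_polyploid")
  if (!all(ok))
    stop("unknown role(s): ", paste(unique(role[!ok]), collapse = ", "))
  structure(
    data.table(individual = individual, population = population, role = role),
    class = c("pop_map", "data.table", "data.frame")
  )
}

# individuals of one or more populations (by label)
pop_individuals <- function(pops, labels) {
  pops$individual[pops$population %in% labels]
}

# check that a popmap covers a table; warn about extras, error on misses
check_popmap <- function(gt, pops) {
  missing <- setdiff(gt$individuals, pops$individual)
  if (length(missing))
    stop("individuals absent from population map: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(pops$individual, gt$individuals)
  if (length(extra))
    pa_log("popmap individuals absent from genotype table: ",
           paste(extra, collapse = ", "), level = "WARN")
  invisible(TRUE)
}

#' Site-filter configuration
#'
#' The two Stacks-style site filters plus the one-SNP-per-locus thinning
#' used before structure-type analyses: `R` is the minimum proportion of
#' genotyped (non-missing) individuals required to keep a site, `min_maf`
#' the minimum minor-allele frequency (computed from pooled allele copies
#' of the pseudo-diploid calls; minor frequency = 1 - frequency of the
#' most common allele). `scope` controls whether `R` is evaluated over
#' the whole cohort or within every population.
#'
#' @param R fraction in `[0, 1]`.
#' @param min_maf fraction in `[0, 0.5]`.
#' @param scope `"overall"` or `"per_population"`.
#' @param one_snp_per_locus keep one seeded-random surviving site per
#'   locus.
#' @param seed integer seed (used only by the one-SNP thinning).
#' @return a `filter_config` list.
#' @export
filter_config <- function(R = 0.5, min_maf = 0, scope = c("overall", "per_population"),
                          one_snp_per_locus = FALSE, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(R >= 0, R <= 1, min_maf >= 0, min_maf <= 0.5,
            is.logical(one_snp_per_locus), length(seed) == 1L)
  structure(
    list(R = R, min_maf = min_maf, scope = scope,
         one_snp_per_locus = isTRUE(one_snp_per_locus),
         seed = as.integer(seed)),
    class = "filter_config"
  )
}
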