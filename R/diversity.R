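#' Population diversity statistics
#'
#' Per-population summary in the style of the standard RADseq
#' population-genetics table: sample size, mean (and s.d.) individuals
#' per locus, observed and expected heterozygosity, the inbreeding
#' coefficient and private-allele counts.
#'
#' Definitions (all from pseudo-diploid calls; each non-missing call
#' contributes two allele copies — a homozygote two of the same, a
#' heterozygote one of each):
#' \itemize{
#' \item `Hobs`: per site, the fraction of non-missing individuals with
#'   two distinct alleles; averaged over sites.
#' \item `Hexp`: per site, `1 - sum(p_a^2)` with `p_a` the
#'   within-population allele frequencies; averaged over sites.
#' \item `FIS`: by default the mean over sites with `Hexp > 0` of
#'   `(Hexp - Hobs) / Hexp` (`fis_method = "mean_of_ratios"`);
#'   alternatively the ratio of site-averaged values
#'   (`"ratio_of_means"`). `NA` when no polymorphic site exists.
#' \item `PA`: number of (site, allele) pairs present in this population
#'   and absent from every other population in the run.
#' \item `N_per_locus`: mean over loci of the number of individuals with
#'   at least one non-missing site in the locus; `PA_per_N` is
#'   `PA / N_per_locus_mean`.
#' }
#'
#' @param gt a (typically filtered) [genotype_table()].
#' @param pops a [pop_map()] covering the table.
#' @param cfg optional [filter_config()]; when supplied,
#'   [filter_sites()] is applied first.
#' @param fis_method site-averaging order for FIS (see Details).
#' @return a data.table with one row per population: `population`, `N`,
#'   `N_per_locus_mean`, `N_per_locus_sd`, `Hobs`, `Hexp`, `FIS`, `PA`,
#'   `PA_per_N`.
#' @export
population_diversity <- function(gt, pops, cfg = NULL,
                                 fis_method = c("mean_of_ratios", "ratio_of_means")) {
  fis_method <- match.arg(fis_method)
  check_popmap(gt, pops)
  if (!is.null(cfg)) gt <- filter_sites(gt, pops, cfg)
  labels <- unique(pops$population)
  sp <- split_calls(gt)
  loci <- gt$sites$locus_id
  pres_by_pop <- lapply(labels, function(p)
    allele_presence(gt, intersect(pop_individuals(pops, p), gt$individuals)))
  names(pres_by_pop) <- labels
  S <- nrow(gt$sites)

  rows <- lapply(labels, function(p) {
    inds <- intersect(pop_individuals(pops, p), gt$individuals)
    n <- length(inds)
    if (n == 0L || S == 0L)
      return(data.table(population = p, N = n,
                        N_per_locus_mean = NA_real_, N_per_locus_sd = NA_real_,
                        Hobs = NA_real_, Hexp = NA_real_, FIS = NA_real_,
                        PA = if (S == 0L) 0L else NA_integer_,
                        PA_per_N = NA_real_))
    a1 <- sp$a1[inds, , drop = FALSE]
    a2 <- sp$a2[inds, , drop = FALSE]
    nm <- colSums(!is.na(a1))
    het <- colSums(a1 != a2, na.rm = TRUE)
    hobs_s <- ifelse(nm > 0, het / nm, NA_real_)
    cnt <- sapply(NUCS, function(a)
      colSums(a1 == a, na.rm = TRUE) + colSums(a2 == a, na.rm = TRUE))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, NUCS))
    tot <- rowSums(cnt)
    hexp_s <- ifelse(tot > 0, 1 - rowSums((cnt / pmax(tot, 1))^2), NA_real_)
    poly <- !is.na(hexp_s) & hexp_s > 0
    fis <- if (!any(poly)) NA_real_ else switch(fis_method,
      mean_of_ratios = mean((hexp_s[poly] - hobs_s[poly]) / hexp_s[poly]),
      ratio_of_means = 1 - mean(hobs_s[poly]) / mean(hexp_s[poly])
    )
    others <- Reduce(`|`, pres_by_pop[setdiff(labels, p)],
                     matrix(FALSE, 4L, S))
    pa <- sum(pres_by_pop[[p]] & !others)
    # individuals per locus: genotyped at >= 1 site of the locus
    npl <- tapply(seq_len(S), loci, function(ix)
      sum(rowSums(!is.na(a1[, ix, drop = FALSE])) > 0))
    data.table(
      population = p, N = n,
      N_per_locus_mean = mean(npl), N_per_locus_sd = stats::sd(npl),
      Hobs = mean(hobs_s, na.rm = TRUE), Hexp = mean(hexp_s, na.rm = TRUE),
      FIS = fis, PA = as.integer(pa),
      PA_per_N = if (mean(npl) > 0) pa / mean(npl) else NA_real_
    )
  })
  rbindlist(rows)
}

#' Per-individual expected heterozygosity
#'
#' Treats each individual as its own unit: after cohort-level filtering,
#' `Hexp_ind` is the mean over the individual's non-missing sites of
#' `1 - sum(p^2)` computed from its own two-allele call — 0.5 at a
#' heterozygous site, 0 at a homozygous one. Under pseudo-diploid calls
#' `Hexp_ind` is therefore bounded by 0.5 and equals half the
#' heterozygous fraction. `n_variant_sites` is the individual's
#' non-missing filtered site count (the "recovered variant sites" used
#' as a coverage proxy by the residual regression).
#'
#' @param gt a [genotype_table()].
#' @param cfg optional [filter_config()] applied first (`R` evaluated
#'   over the full cohort).
#' @return a data.table `individual`, `n_variant_sites`, `Hexp_ind`
#'   (`NA` when the individual has no non-missing site, logged).
#' @export
individual_hexp <- function(gt, cfg = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.null(cfg)) gt <- filter_sites(gt, NULL, cfg)
  sp <- split_calls(gt)
  nonmiss <- !is.na(sp$a1)
  n_sites <- rowSums(nonmiss)
  het <- rowSums(sp$a1 != sp$a2, na.rm = TRUE)
  hexp <- ifelse(n_sites > 0, 0.5 * het / n_sites, NA_real_)
  if (any(n_sites == 0))
    pa_log(sum(n_sites == 0), " individual(s) with 0 non-missing sites -> NA")
  data.table(individual = gt$individuals,
             n_variant_sites = as.integer(n_sites), Hexp_ind = hexp)
}
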