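#' Filter variant sites
#'
#' Applies the three Stacks-style site filters of a [filter_config()] in
#' order: (a) a site is kept iff the proportion of non-missing
#' individuals is at least `R` — over the whole cohort
#' (`scope = "overall"`) or within every non-empty population
#' (`scope = "per_population"`); (b) the overall minor-allele frequency
#' (1 minus the frequency of the most common allele, from pooled allele
#' copies of the pseudo-diploid calls) must be at least `min_maf`; (c)
#' with `one_snp_per_locus`, one seeded-random site is kept per locus
#' among the survivors.
#'
#' May return an empty table (logged), never an error.
#'
#' @param gt a [genotype_table()].
#' @param pops a [pop_map()] (needed for `scope = "per_population"`).
#' @param cfg a [filter_config()].
#' @return the filtered [genotype_table()].
#' @export
filter_sites <- function(gt, pops = NULL, cfg = filter_config()) {
  stopifnot(inherits(gt, "genotype_table"), inherits(cfg, "filter_config"))
  calls <- gt$calls
  S <- ncol(calls)
  nonmiss <- !is.na(calls)

  if (cfg$scope == "overall" || is.null(pops)) {
    keep_r <- colMeans(nonmiss) >= cfg$R
  } else {
    keep_r <- rep(TRUE, S)
    for (p in unique(pops$population)) {
      inds <- intersect(pop_individuals(pops, p), gt$individuals)
      if (!length(inds)) next
      keep_r <- keep_r &
        colMeans(nonmiss[inds, , drop = FALSE]) >= cfg$R
    }
  }

  sp <- split_calls(gt)
  cnt <- sapply(NUCS, function(a)
    colSums(sp$a1 == a, na.rm = TRUE) + colSums(sp$a2 == a, na.rm = TRUE))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, NUCS))
  tot <- rowSums(cnt)
  maf <- ifelse(tot > 0, 1 - apply(cnt, 1L, max) / tot, 0)
  keep <- keep_r & maf >= cfg$min_maf

  if (cfg$one_snp_per_locus) {
    set.seed(child_seed(cfg$seed, "one_snp_per_locus"))
    surv <- which(keep)
    keep2 <- logical(S)
    for (li in unique(gt$sites$locus_id[surv])) {
      cand <- surv[gt$sites$locus_id[surv] == li]
      keep2[if (length(cand) == 1L) cand else sample(cand, 1L)] <- TRUE
    }
    keep <- keep2
  }
  if (!any(keep)) pa_log("filter_sites: no sites survived", level = "WARN")
  subset_table(gt, site_ids = gt$sites$site_id[keep])
}
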