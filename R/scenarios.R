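#' Canonical simulation scenarios
#'
#' Fixed, documented simulation worlds used by the package's
#' property-based validation (and usable as worked examples). Each
#' returns a [simulation_config()]; only the seed varies. Parameter
#' choices are discussed in the package vignette.
#'
#' \describe{
#' \item{scenario_introgression}{K = 3 ancestral taxa, 2000 loci (one
#'   SNP each), private-allele supply 0.05; four derived sexual
#'   populations of 10 tetraploids whose ancestry weight for the donor
#'   taxon T1 is 0, 0.05, 0.1 and 0.2. Used for rank-recovery and
#'   group-separation checks of the tracer.}
#' \item{scenario_ghost}{as above but with an extinct ("ghost") taxon
#'   that reaches the data only through a proxy polyploid population
#'   (half ghost, half T1) and through one introgressed derived
#'   population; `ghost_on = FALSE` keeps the same proxy mixture but
#'   removes the ghost (null world for false-positive bounds).}
#' \item{scenario_normalization}{constant donor weight 0.1 in all 400
#'   derived individuals but per-individual missingness uniform in
#'   `[0.1, 0.6]`: the traced proportion must not correlate with the
#'   number of recovered variant sites. 400 individuals so that the
#'   sample correlation (null s.d. ~ 0.05) resolves the 0.1 band.}
#' \item{scenario_affinity}{3 taxa, 800 loci of 4 SNPs (60 bp), donor
#'   weight 0.25 vs 0 in two derived populations; exercises
#'   pseudoreference mapping affinity.}
#' \item{scenario_gradient}{5 derived populations of 30 at 10-90 km from
#'   the contact line, an imposed expected-heterozygosity decline of
#'   5e-4 per km, and a moderate coverage confound (per-individual
#'   latent coverage rising with distance; low coverage inflates both
#'   missingness and heterozygote dropout).}
#' }
#'
#' @param seed integer seed.
#' @param ghost_on logical (scenario_ghost): include the ghost taxon.
#' @return a `sim_config`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_introgression <- function(seed) {
  simulation_config(
    n_ancestors = 3, loci = 2000, sites_per_locus = 1, private_rate = 0.05,
    ancestral_n = 10,
    derived = list(
      list(label = "D00", n = 10, weights = c(T1 = 0)),
      list(label = "D05", n = 10, weights = c(T1 = 0.05)),
      list(label = "D10", n = 10, weights = c(T1 = 0.10)),
      list(label = "D20", n = 10, weights = c(T1 = 0.20))
    ),
    missing_rate_range = c(0.05, 0.15), seed = seed
  )
}

#' @rdname scenarios
#' @export
scenario_ghost <- function(seed, ghost_on = TRUE) {
  simulation_config(
    n_ancestors = 3, loci = 2000, sites_per_locus = 1, private_rate = 0.05,
    ancestral_n = 10,
    include_extinct = ghost_on, ghost_private_rate = 0.05,
    derived = list(
      list(label = "Dgh", n = 10,
           weights = if (ghost_on) c(ghost = 0.15, T2 = 0.1) else c(T2 = 0.1))
    ),
    proxy = list(label = "Proxy", n = 10,
                 weights = if (ghost_on) c(ghost = 0.5, T1 = 0.5) else c(T1 = 0.5)),
    missing_rate_range = c(0.05, 0.15), seed = seed
  )
}

#' @rdname scenarios
#' @export
scenario_normalization <- function(seed) {
  simulation_config(
    n_ancestors = 3, loci = 2000, sites_per_locus = 1, private_rate = 0.05,
    ancestral_n = 10,
    derived = list(list(label = "D", n = 400, weights = c(T1 = 0.1))),
    missing_rate_range = c(0.1, 0.6), seed = seed
  )
}

#' @rdname scenarios
#' @export
scenario_affinity <- function(seed) {
  simulation_config(
    n_ancestors = 3, loci = 800, sites_per_locus = 4, seq_len = 60,
    private_rate = 0.05, ancestral_n = 6,
    derived = list(
      list(label = "Dn", n = 10, weights = c(T1 = 0)),
      list(label = "Dd", n = 10, weights = c(T1 = 0.25))
    ),
    missing_rate_range = c(0.05, 0.15), seed = seed
  )
}

#' @rdname scenarios
#' @export
scenario_gradient <- function(seed) {
  simulation_config(
    n_ancestors = 2, loci = 1500, sites_per_locus = 1, ancestral_n = 5,
    derived = lapply(1:5, function(i)
      list(label = paste0("P", i), n = 30, weights = c(T1 = 0.05))),
    geo = list(pop_distances_km = c(10, 30, 50, 70, 90)),
    gradient_slope = 5e-4,
    coverage_confound = list(base = 0.3, per_km = 0.003, sd = 0.3,
                             dropout_max = 0.25, missing_max = 0.5),
    missing_rate_range = c(0.05, 0.15), seed = seed
  )
}
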