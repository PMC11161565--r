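#' Simulation configuration
#'
#' Describes the generative world the analysis modules assume: `K`
#' extant ancestral diploid taxa each carrying taxon-private alleles at a
#' supply rate `pi`, an optional extinct ("ghost") ancestor that emits no
#' diploid samples but contributes to derived populations and to a
#' polyploid proxy population, derived tetraploid populations with
#' per-individual ancestry weights over (taxa, ghost, base pool),
#' optional clonal (apomictic) population structure, coverage-driven
#' missingness, and a geographic sexual/apomict contact line with
#' population clouds at increasing distances.
#'
#' @param n_ancestors K, number of extant ancestral diploid taxa (>= 2).
#' @param loci number of RAD loci.
#' @param sites_per_locus variant sites per locus.
#' @param seq_len locus sequence length in bp (>= sites_per_locus).
#' @param private_rate per-taxon probability that a site receives a
#'   taxon-unique allele; scalar or length-K vector, each in `[0, 0.5]`.
#' @param ancestral_n diploid samples per ancestral taxon (scalar or
#'   length-K).
#' @param derived list of derived-population descriptions, each a list
#'   with `label`, `n`, `weights` (named non-negative vector over taxon
#'   names, optionally `"ghost"`, and `"base"`, summing to 1; missing
#'   mass is assigned to `"base"`), and optionally `clonal = TRUE`,
#'   `clone_mutation_rate` (epsilon, in `[0, 0.01]`), `clone_groups`.
#' @param include_extinct simulate a ghost taxon; implies a proxy
#'   population.
#' @param ghost_private_rate private-allele supply of the ghost taxon.
#' @param proxy list(`label`, `n`, `weights`) for the proxy_polyploid
#'   population (default: half ghost, half first extant taxon).
#' @param missing_rate_range `c(lo, hi)`: per-individual missingness is
#'   drawn uniformly from this range.
#' @param dirichlet_alpha concentration of the per-taxon allele-frequency
#'   draw at each site (symmetric Dirichlet over the two base alleles).
#' @param geo list: `border_lat` (the contact line runs west-east at this
#'   latitude), `border_lon` range, `pop_distances_km` (per derived
#'   population, distance of its cloud center south of the line; default
#'   evenly spaced 5-100 km), `cloud_sd_km`.
#' @param gradient_slope expected decline of individual expected
#'   heterozygosity per km of distance from the contact line (0 = off).
#'   Imposed by thinning heterozygous calls of derived non-clonal
#'   individuals so that E\[Hexp_ind\] drops by `gradient_slope` per km.
#' @param coverage_confound `NULL`, or a list(`base`, `per_km`, `sd`,
#'   `dropout_max`, `missing_max`) tying a latent per-individual coverage
#'   to distance: low coverage raises both missingness and heterozygote
#'   dropout (het calls observed as homozygous), reproducing the
#'   coverage-heterozygosity confound that the residual regression
#'   corrects.
#' @param seed mandatory integer seed.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_ancestors = 3L,
                              loci = 500L,
                              sites_per_locus = 1L,
                              seq_len = 80L,
                              private_rate = 0.05,
                              ancestral_n = 10L,
                              derived = NULL,
                              include_extinct = FALSE,
                              ghost_private_rate = 0.05,
                              proxy = NULL,
                              missing_rate_range = c(0.05, 0.15),
                              dirichlet_alpha = 1,
                              geo = list(),
                              gradient_slope = 0,
                              coverage_confound = NULL,
                              seed) {
  if (missing(seed)) stop("simulation requires a seed")
  K <- as.integer(n_ancestors)
  if (K < 2L) stop("need at least 2 ancestral taxa")
  taxa <- paste0("T", seq_len(K))
  private_rate <- rep_len(private_rate, K)
  if (any(private_rate < 0 | private_rate > 0.5))
    stop("private_rate must be in [0, 0.5]")
  ancestral_n <- rep_len(as.integer(ancestral_n), K)
  if (is.null(derived))
    derived <- list(list(label = "D1", n = 20L,
                         weights = c(stats::setNames(rep(0.1, K), taxa))))
  sources <- c(taxa, if (include_extinct) "ghost", "base")
  derived <- lapply(derived, function(d) {
    d$label <- as.character(d$label)
    d$n <- as.integer(d$n)
    w <- unlist(d$weights %||% numeric(0))  # tolerate JSON named lists
    if (is.null(names(w)) && length(w)) stop("derived weights must be named")
    unknown <- setdiff(names(w), sources)
    if (length(unknown))
      stop("unknown weight source(s) for ", d$label, ": ",
           paste(unknown, collapse = ", "))
    full <- stats::setNames(rep(0, length(sources)), sources)
    full[names(w)] <- w
    if (any(full < 0)) stop("ancestry weights must be non-negative")
    if (!"base" %in% names(w)) full["base"] <- max(0, 1 - sum(full))
    if (abs(sum(full) - 1) > 1e-8)
      stop("ancestry weights must sum to 1 (population ", d$label, ")")
    d$weights <- full
    d$clonal <- isTRUE(d$clonal)
    d$clone_mutation_rate <- d$clone_mutation_rate %||% 0
    if (d$clone_mutation_rate < 0 || d$clone_mutation_rate > 0.01)
      stop("clone_mutation_rate must be in [0, 0.01]")
    d$clone_groups <- as.integer(d$clone_groups %||% max(1L, d$n %/% 5L))
    d
  })
  if (include_extinct && is.null(proxy))
    proxy <- list(label = "Proxy", n = 10L,
                  weights = c(ghost = 0.5, stats::setNames(0.5, taxa[1])))
  if (!is.null(proxy)) {
    proxy$weights <- unlist(proxy$weights)
    unknown <- setdiff(names(proxy$weights), sources)
    if (length(unknown))
      stop("unknown proxy weight source(s): ", paste(unknown, collapse = ", "))
    full <- stats::setNames(rep(0, length(sources)), sources)
    full[names(proxy$weights)] <- proxy$weights
    if (!"base" %in% names(proxy$weights)) full["base"] <- max(0, 1 - sum(full))
    if (abs(sum(full) - 1) > 1e-8) stop("proxy weights must sum to 1")
    proxy$weights <- full
    proxy$n <- as.integer(proxy$n)
  }
  missing_rate_range <- unlist(missing_rate_range)
  if (is.list(geo)) geo <- lapply(geo, unlist)
  if (is.list(coverage_confound)) coverage_confound <- lapply(coverage_confound, unlist)
  stopifnot(length(missing_rate_range) == 2L,
            missing_rate_range[1] >= 0, missing_rate_range[2] <= 1,
            missing_rate_range[1] <= missing_rate_range[2])
  if (sites_per_locus > seq_len) stop("sites_per_locus must be <= seq_len")
  geo <- utils::modifyList(list(
    border_lat = 48, border_lon = c(8, 20), n_border_points = 25L,
    pop_distances_km = NULL, cloud_sd_km = 5
  ), geo)
  structure(list(
    K = K, taxa = taxa, loci = as.integer(loci),
    sites_per_locus = as.integer(sites_per_locus),
    seq_len = as.integer(seq_len),
    private_rate = private_rate, ancestral_n = ancestral_n,
    derived = derived, include_extinct = isTRUE(include_extinct),
    ghost_private_rate = ghost_private_rate, proxy = proxy,
    missing_rate_range = missing_rate_range,
    dirichlet_alpha = dirichlet_alpha, geo = geo,
    gradient_slope = gradient_slope,
    coverage_confound = coverage_confound,
    seed = as.integer(seed)
  ), class = "sim_config")
}

rdirichlet2 <- function(n, alpha) {
  g1 <- stats::rgamma(n, alpha)
  g2 <- stats::rgamma(n, alpha)
  g1 / (g1 + g2)
}

#' Simulate a full dataset with ground truth
#'
#' Generative model, fully seeded. (1) Per locus an ancestral base
#' sequence; per site two base alleles, and for each source (extant
#' taxon, optional ghost, base pool) allele frequencies drawn from a
#' symmetric Dirichlet over the base alleles; with probability `pi_k` a
#' taxon-unique third allele at frequency in `[0.2, 0.8]` replaces one
#' base allele in taxon k only (injected privates are pairwise disjoint
#' across taxa by construction). (2) Ancestral diploids draw two copies
#' from their taxon's frequencies. (3) Derived tetraploids draw four
#' copies, each copy's source taxon categorical in the individual's
#' ancestry weights; the pseudo-diploid collapse keeps the two most
#' frequent distinct alleles among the four copies (ties broken by a
#' seeded uniform pick). (4) Clonal populations: one founder genotype per
#' clone group; members copy it with per-site alteration probability
#' epsilon. (5) Optional heterozygosity-distance gradient and coverage
#' confound (see [simulation_config()]); then each call is set missing
#' with the individual's missingness rate. (6) Locus consensus sequences
#' carry one allele of each call at the variant columns (N when
#' missing). (7) Coordinates place population clouds at increasing
#' distances from a straight contact line.
#'
#' @param config a [simulation_config()].
#' @return a list of class `sim_dataset`: `table` ([genotype_table()]),
#'   `seqs` ([locus_seqset()]), `popmap` ([pop_map()]), `coords`,
#'   `borderline`, and `truth` (list: `individuals` data.table with
#'   ancestry weights, clone group, missingness, distance; `private`
#'   data.table of injected (taxon, site_id, allele); `gradient_slope`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(child_seed(cfg$seed, "simulate"))
  K <- cfg$K
  taxa <- cfg$taxa
  has_ghost <- cfg$include_extinct
  sources <- c(taxa, if (has_ghost) "ghost", "base")
  Tn <- length(sources)
  S <- cfg$loci * cfg$sites_per_locus
  locus_id <- rep(paste0("L", seq_len(cfg$loci)), each = cfg$sites_per_locus)
  # place site columns within the locus sequence (distinct, sorted)
  colmat <- t(vapply(seq_len(cfg$loci), function(i)
    sort(sample.int(cfg$seq_len, cfg$sites_per_locus)) - 1L,
    integer(cfg$sites_per_locus)))
  column <- as.integer(t(colmat))
  site_id <- paste0(locus_id, "_", column)
  chrom <- rep("chr1", S)
  pos <- as.integer((rep(seq_len(cfg$loci), each = cfg$sites_per_locus) - 1L) *
                      1000L + column + 1L)

  # --- per-site allele frequencies -----------------------------------
  base_pair <- t(vapply(seq_len(S), function(s) sample.int(4L, 2L),
                        integer(2)))
  freq <- array(0, c(S, Tn, 4L), dimnames = list(NULL, sources, NUCS))
  for (t in seq_len(Tn)) {
    f1 <- rdirichlet2(S, cfg$dirichlet_alpha)
    freq[cbind(seq_len(S), t, base_pair[, 1])] <- f1
    freq[cbind(seq_len(S), t, base_pair[, 2])] <- 1 - f1
  }
  # inject taxon-private alleles (disjoint across taxa at each site)
  pi_all <- c(cfg$private_rate, if (has_ghost) cfg$ghost_private_rate)
  priv_taxa <- c(taxa, if (has_ghost) "ghost")
  taken <- matrix(FALSE, S, 4L)  # private alleles already claimed per site
  taken[cbind(seq_len(S), base_pair[, 1])] <- TRUE
  taken[cbind(seq_len(S), base_pair[, 2])] <- TRUE
  truth_priv <- list()
  for (k in seq_along(priv_taxa)) {
    hit <- which(runif(S) < pi_all[k])
    for (s in hit) {
      free <- which(!taken[s, ])
      if (!length(free)) next
      a <- if (length(free) == 1L) free else sample(free, 1L)
      taken[s, a] <- TRUE
      f <- runif(1, 0.2, 0.8)
      replaced <- base_pair[s, sample.int(2L, 1L)]
      keep <- setdiff(base_pair[s, ], replaced)
      freq[s, k, ] <- 0
      freq[s, k, a] <- f
      freq[s, k, keep] <- 1 - f
      truth_priv[[length(truth_priv) + 1L]] <-
        data.table(taxon = priv_taxa[k], site_id = site_id[s], allele = NUCS[a])
    }
  }
  truth_priv <- if (length(truth_priv)) rbindlist(truth_priv) else
    data.table(taxon = character(), site_id = character(), allele = character())
  # injected privates are disjoint across taxa by construction
  stopifnot(!anyDuplicated(truth_priv[, c("site_id", "allele")]))
  # cumulative frequencies for fast inverse-CDF draws
  cum1 <- freq[, , 1L]
  cum2 <- cum1 + freq[, , 2L]
  cum3 <- cum2 + freq[, , 3L]
  dim(cum1) <- dim(cum2) <- dim(cum3) <- c(S, Tn)

  draw_copies <- function(src) {
    # src: integer vector (length n_copies * S) of source columns;
    # returns allele ints drawn from the per-site source frequencies
    n <- length(src) / S
    s <- rep(seq_len(S), n)
    u <- runif(length(src))
    ij <- cbind(s, src)
    1L + (u > cum1[ij]) + (u > cum2[ij]) + (u > cum3[ij])
  }

  collapse4 <- function(copies) {
    # copies: S x 4 integer matrix -> pseudo-diploid (a1, a2) ints
    sc <- matrix(-1, S, 4L)
    for (a in 1:4) {
      n_a <- rowSums(copies == a)
      sc[, a] <- ifelse(n_a > 0, n_a + runif(S) * 0.9, -1)
    }
    m1 <- pmax(sc[, 1], sc[, 2], sc[, 3], sc[, 4])
    al1 <- max.col(sc == m1, ties.method = "first")
    sc[cbind(seq_len(S), al1)] <- -2
    m2 <- pmax(sc[, 1], sc[, 2], sc[, 3], sc[, 4])
    al2 <- ifelse(m2 > 0, max.col(sc == m2, ties.method = "first"), al1)
    cbind(al1, al2)
  }

  # --- individuals ---------------------------------------------------
  inds <- character(0); pop <- character(0); role <- character(0)
  W <- NULL          # ancestry weight rows (over `sources`)
  clone_grp <- character(0)
  geno <- list()     # per individual: S x 2 integer allele matrix

  add_ind <- function(id, p, r, w, cg, g) {
    inds <<- c(inds, id); pop <<- c(pop, p); role <<- c(role, r)
    W <<- rbind(W, w); clone_grp <<- c(clone_grp, cg)
    geno[[id]] <<- g
  }

  for (k in seq_len(K)) {
    w <- stats::setNames(rep(0, Tn), sources); w[k] <- 1
    for (i in seq_len(cfg$ancestral_n[k])) {
      src <- rep(k, 2L * S)
      cp <- matrix(draw_copies(src), S, 2L)
      add_ind(sprintf("%s_%02d", taxa[k], i), taxa[k], "ancestral", w,
              NA_character_, cp)
    }
  }
  sim_polyploid <- function(w) {
    src <- sample.int(Tn, 4L * S, replace = TRUE, prob = w)
    copies <- matrix(draw_copies(src), S, 4L)
    collapse4(copies)
  }
  for (d in cfg$derived) {
    if (d$clonal) {
      groups <- rep(seq_len(d$clone_groups), length.out = d$n)
      founders <- lapply(seq_len(d$clone_groups), function(g) sim_polyploid(d$weights))
      for (i in seq_len(d$n)) {
        g <- founders[[groups[i]]]
        eps <- d$clone_mutation_rate
        if (eps > 0) {
          mut <- which(runif(S) < eps)
          if (length(mut)) {
            slot <- sample.int(2L, length(mut), replace = TRUE)
            g[cbind(mut, slot)] <- sample.int(4L, length(mut), replace = TRUE)
          }
        }
        add_ind(sprintf("%s_%02d", d$label, i), d$label, "derived", d$weights,
                paste0(d$label, "_c", groups[i]), g)
      }
    } else {
      for (i in seq_len(d$n))
        add_ind(sprintf("%s_%02d", d$label, i), d$label, "derived", d$weights,
                NA_character_, sim_polyploid(d$weights))
    }
  }
  if (!is.null(cfg$proxy)) {
    for (i in seq_len(cfg$proxy$n))
      add_ind(sprintf("%s_%02d", cfg$proxy$label, i), cfg$proxy$label,
              "proxy_polyploid", cfg$proxy$weights, NA_character_,
              sim_polyploid(cfg$proxy$weights))
  }
  n_ind <- length(inds)
  rownames(W) <- inds

  # --- geography -----------------------------------------------------
  g <- cfg$geo
  border <- data.table(
    lat = rep(g$border_lat, g$n_border_points),
    lon = seq(g$border_lon[1], g$border_lon[2], length.out = g$n_border_points)
  )
  pops_all <- unique(pop)
  derived_labels <- vapply(cfg$derived, `[[`, character(1), "label")
  dist_km <- stats::setNames(rep(150, length(pops_all)), pops_all)  # ancestors far
  dd <- g$pop_distances_km %||% seq(5, 100, length.out = length(derived_labels))
  dist_km[derived_labels] <- rep_len(dd, length(derived_labels))
  if (!is.null(cfg$proxy)) dist_km[cfg$proxy$label] <- 120
  lon_centers <- stats::setNames(
    seq(g$border_lon[1] + 1, g$border_lon[2] - 1, length.out = length(pops_all)),
    pops_all)
  km_per_deg <- pi * 6371 / 180
  lat_i <- g$border_lat - dist_km[pop] / km_per_deg +
    rnorm(n_ind, 0, g$cloud_sd_km / km_per_deg)
  lon_i <- lon_centers[pop] +
    rnorm(n_ind, 0, g$cloud_sd_km / (km_per_deg * cos(g$border_lat * pi / 180)))
  coords <- data.table(individual = inds, lat = lat_i, lon = lon_i)
  d_ind <- distance_to_borderline(coords, border)$distance_km

  # --- gradient thinning and coverage confound -----------------------
  is_het <- function(g) g[, 1] != g[, 2]
  grad_targets <- role == "derived" &
    !vapply(cfg$derived[match(pop, derived_labels)], function(d)
      if (is.null(d)) FALSE else d$clonal, logical(1))
  if (cfg$gradient_slope > 0) {
    for (i in which(grad_targets)) {
      gmat <- geno[[inds[i]]]
      het <- which(is_het(gmat))
      h <- length(het) / S
      if (h <= 0) next
      p_thin <- min(1, cfg$gradient_slope * d_ind[i] / (0.5 * h))
      thin <- het[runif(length(het)) < p_thin]
      if (length(thin)) {
        pick <- sample.int(2L, length(thin), replace = TRUE)
        gmat[thin, ] <- gmat[cbind(thin, pick)]
        geno[[inds[i]]] <- gmat
      }
    }
  }
  m_i <- runif(n_ind, cfg$missing_rate_range[1], cfg$missing_rate_range[2])
  if (!is.null(cfg$coverage_confound)) {
    cc <- cfg$coverage_confound
    u <- pmin(1, pmax(0.05, cc$base + cc$per_km * d_ind + rnorm(n_ind, 0, cc$sd)))
    drop_i <- cc$dropout_max * (1 - u)
    m_i <- ifelse(grad_targets, cc$missing_max * (1 - u), m_i)
    for (i in which(grad_targets)) {
      gmat <- geno[[inds[i]]]
      het <- which(is_het(gmat))
      dr <- het[runif(length(het)) < drop_i[i]]
      if (length(dr)) {
        pick <- sample.int(2L, length(dr), replace = TRUE)
        gmat[dr, ] <- gmat[cbind(dr, pick)]
        geno[[inds[i]]] <- gmat
      }
    }
  }

  # --- assemble calls with missingness -------------------------------
  calls <- matrix(NA_character_, n_ind, S, dimnames = list(inds, site_id))
  for (i in seq_len(n_ind)) {
    gmat <- geno[[inds[i]]]
    cc <- canon_call(NUCS[gmat[, 1]], NUCS[gmat[, 2]])
    cc[runif(S) < m_i[i]] <- NA_character_
    calls[i, ] <- cc
  }
  gt <- genotype_table(
    inds,
    data.frame(site_id = site_id, locus_id = locus_id, column = column,
               chrom = chrom, pos = pos),
    calls
  )
  popmap <- pop_map(inds, pop, role)

  # --- locus sequences ----------------------------------------------
  base_seq <- vapply(seq_len(cfg$loci), function(i)
    paste(NUCS[sample.int(4L, cfg$seq_len, replace = TRUE)], collapse = ""),
    character(1))
  locus_of <- rep(seq_len(cfg$loci), each = cfg$sites_per_locus)
  seq_rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    cc <- calls[i, ]
    nonmiss_by_locus <- tapply(!is.na(cc), locus_of, any)
    present <- which(nonmiss_by_locus)
    if (!length(present)) { seq_rows[[i]] <- NULL; next }
    a1 <- sub("/.*$", "", cc); a2 <- sub("^.*/", "", cc)
    pick2 <- runif(S) < 0.5
    al <- ifelse(is.na(cc), "N", ifelse(pick2, a2, a1))
    seqs_i <- character(length(present))
    for (j in seq_along(present)) {
      li <- present[j]
      chars <- strsplit(base_seq[li], "")[[1]]
      sidx <- which(locus_of == li)
      chars[column[sidx] + 1L] <- al[sidx]
      seqs_i[j] <- paste(chars, collapse = "")
    }
    seq_rows[[i]] <- data.table(locus_id = paste0("L", present),
                                individual = inds[i], seq = seqs_i)
  }
  seq_dt <- rbindlist(seq_rows[!vapply(seq_rows, is.null, logical(1))])
  seqs <- locus_seqset(seq_dt$locus_id, seq_dt$individual, seq_dt$seq)

  truth_ind <- data.table(
    individual = inds, population = pop, role = role,
    clone_group = clone_grp, missing_rate = m_i, distance_km = d_ind
  )
  for (s in sources) truth_ind[[paste0("w_", s)]] <- unname(W[, s])

  structure(list(
    table = gt, seqs = seqs, popmap = popmap, coords = coords,
    borderline = border,
    truth = list(individuals = truth_ind, private = truth_priv,
                 gradient_slope = cfg$gradient_slope, sources = sources)
  ), class = "sim_dataset")
}

#' Rank correlation between true ancestry weight and traced proportion
#'
#' Parameter-recovery metric: Spearman correlation, across derived
#' individuals, between the true simulated ancestry weight for one
#' ancestor and the traced private-allele proportion for that ancestor.
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param trace a trace matrix from [trace_private_alleles()] computed on
#'   the same dataset.
#' @param ancestor taxon label (a simulated source, e.g. `"T1"` or
#'   `"ghost"`).
#' @return Spearman rho; `NA` with attribute `reason` when the true
#'   weights are constant (correlation undefined).
#' @export
truth_introgression_rank <- function(truth, trace, ancestor) {
  wcol <- paste0("w_", ancestor)
  if (!wcol %in% names(truth$individuals)) stop("unknown ancestor: ", ancestor)
  keep_row <- trace$ancestor == ancestor  # resolve outside data.table scope
  tr <- as.data.table(trace)[keep_row]
  m <- merge(truth$individuals[, c("individual", wcol), with = FALSE], tr,
             by = "individual")
  m <- m[!is.na(m$proportion)]
  if (nrow(m) < 3L) stop("need >= 3 traced individuals")
  w <- m[[wcol]]
  if (stats::sd(w) == 0)
    return(structure(NA_real_, reason = "constant true weights"))
  cor(w, m$proportion, method = "spearman")
}
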