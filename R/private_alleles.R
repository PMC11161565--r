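#' Build a per-ancestor private-allele catalogue
#'
#' An allele `a` at site `s` is private to ancestral taxon `k` iff it
#' occurs in at least one non-missing call of `k` and in no non-missing
#' call of any other listed ancestor. The privacy universe is the listed
#' ancestral taxa only — derived and proxy populations never veto
#' privacy, because derived taxa are expected to share ancestral
#' alleles.
#'
#' An ancestor entirely missing at a site cannot be excluded as a
#' carrier. By default (`mode = "optimistic"`) such sites still admit
#' privates for the other taxa; `mode = "strict"` skips a site unless
#' every listed ancestor has at least one non-missing call there.
#'
#' @param gt a [genotype_table()] (the filtered site universe).
#' @param pops a [pop_map()]; every listed ancestor must be a population
#'   label in it with at least one genotyped individual.
#' @param ancestors character vector of ancestral taxon labels.
#' @param mode `"optimistic"` (default) or `"strict"` (see Details).
#' @return a `pa_catalog`: data.table `taxon`, `site_id`, `allele`,
#'   `provenance` (here always `"extant"`), with attributes `ancestors`
#'   and `mode`. Empty catalogue is a warning, not an error.
#' @export
build_catalog <- function(gt, pops, ancestors,
                          mode = c("optimistic", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "genotype_table"))
  missing_anc <- setdiff(ancestors, pops$population)
  if (length(missing_anc))
    stop("ancestor label(s) absent from popmap: ",
         paste(missing_anc, collapse = ", "))
  pres <- lapply(ancestors, function(k) {
    inds <- intersect(pop_individuals(pops, k), gt$individuals)
    if (!length(inds)) stop("ancestor ", k, " has no genotyped individual")
    allele_presence(gt, inds)
  })
  names(pres) <- ancestors
  S <- nrow(gt$sites)
  typed <- if (mode == "strict") {
    # site usable only if every ancestor has >= 1 non-missing call
    Reduce(`&`, lapply(ancestors, function(k) {
      inds <- intersect(pop_individuals(pops, k), gt$individuals)
      colSums(!is.na(gt$calls[inds, , drop = FALSE])) > 0
    }))
  } else rep(TRUE, S)
  rows <- lapply(ancestors, function(k) {
    others <- Reduce(`|`, pres[setdiff(ancestors, k)],
                     matrix(FALSE, 4L, S))
    hit <- pres[[k]] & !others & rep(typed, each = 4L)
    ij <- which(hit, arr.ind = TRUE)
    if (!nrow(ij)) return(NULL)
    data.table(taxon = k, site_id = gt$sites$site_id[ij[, 2]],
               allele = NUCS[ij[, 1]], provenance = "extant")
  })
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) {
    pa_log("empty private-allele catalogue", level = "WARN")
    out <- data.table(taxon = character(), site_id = character(),
                      allele = character(), provenance = character())
  }
  structure(out, class = c("pa_catalog", class(out)),
            ancestors = ancestors, mode = mode)
}

#' Attribute proxy-population alleles to an extinct ancestor
#'
#' A polyploid hybrid complex can carry a subgenome from an ancestor
#' with no extant diploid representatives (a ghost lineage). Alleles
#' present in a designated proxy polyploid population and absent from
#' every extant ancestral taxon are attributed to that extinct ancestor
#' and traced separately. Such alleles may — and are expected to —
#' overlap the derived populations' alleles; only the extant ancestors
#' exclude.
#'
#' @param gt a [genotype_table()].
#' @param pops a [pop_map()]; `proxy_pop` must exist with role
#'   `proxy_polyploid`.
#' @param proxy_pop population label of the proxy.
#' @param extant_ancestors labels of the extant ancestral taxa.
#' @param label taxon label for the attributed catalogue entry (default
#'   `"<proxy_pop>_extinct"`).
#' @return a `pa_catalog` with provenance `"extinct_attributed"`.
#' @export
attribute_extinct <- function(gt, pops, proxy_pop, extant_ancestors,
                              label = paste0(proxy_pop, "_extinct")) {
  stopifnot(inherits(gt, "genotype_table"))
  prole <- pops$role[pops$population == proxy_pop]
  if (!length(prole)) stop("proxy population not in popmap: ", proxy_pop)
  if (!all(prole == "proxy_polyploid"))
    stop(proxy_pop, " does not have role proxy_polyploid")
  proxy_inds <- intersect(pop_individuals(pops, proxy_pop), gt$individuals)
  if (!length(proxy_inds)) stop("proxy population has no genotyped individual")
  S <- nrow(gt$sites)
  proxy_pres <- allele_presence(gt, proxy_inds)
  extant <- Reduce(`|`, lapply(extant_ancestors, function(k)
    allele_presence(gt, intersect(pop_individuals(pops, k), gt$individuals))),
    matrix(FALSE, 4L, S))
  hit <- proxy_pres & !extant
  ij <- which(hit, arr.ind = TRUE)
  out <- if (nrow(ij))
    data.table(taxon = label, site_id = gt$sites$site_id[ij[, 2]],
               allele = NUCS[ij[, 1]], provenance = "extinct_attributed")
  else data.table(taxon = character(), site_id = character(),
                  allele = character(), provenance = character())
  structure(out, class = c("pa_catalog", class(out)),
            ancestors = extant_ancestors, mode = "optimistic")
}

#' Combine catalogues
#'
#' Binds an extant catalogue and extinct-attributed entries into one
#' catalogue for joint tracing.
#'
#' @param ... `pa_catalog` objects.
#' @return a `pa_catalog`.
#' @export
combine_catalogs <- function(...) {
  parts <- list(...)
  out <- rbindlist(lapply(parts, as.data.table))
  structure(out, class = c("pa_catalog", class(out)),
            ancestors = unique(unlist(lapply(parts, attr, "ancestors"))),
            mode = "combined")
}

#' Write / read a private-allele catalogue (TSV)
#'
#' @param catalog a `pa_catalog`.
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  fwrite(as.data.table(catalog), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = 1:4))
  need <- c("taxon", "site_id", "allele", "provenance")
  if (!all(need %in% names(dt)))
    stop("catalogue file needs columns: ", paste(need, collapse = ", "))
  structure(dt, class = c("pa_catalog", class(dt)),
            ancestors = unique(dt$taxon[dt$provenance == "extant"]),
            mode = "file")
}

#' Trace catalogued private alleles through derived individuals
#'
#' For each target individual and each catalogued ancestor, counts the
#' catalogue (site, allele) pairs whose allele is present in the
#' target's non-missing call at that site. Presence is counted once per
#' (site, allele) — dosage is unknowable from pseudo-diploid calls. The
#' count is normalized by the individual's recovered variant sites (its
#' non-missing sites in the filtered table), which removes the effect of
#' unequal coverage and missing data; the proportion is `NA` iff the
#' individual has no recovered site.
#'
#' @param gt the [genotype_table()] the catalogue was built on (same
#'   site universe).
#' @param catalog a `pa_catalog` from [build_catalog()] /
#'   [attribute_extinct()] / [combine_catalogs()].
#' @param targets character vector of derived individual ids.
#' @param pops optional [pop_map()]; when given, a target belonging to a
#'   catalogued ancestral taxon is an error (it would contaminate the
#'   privacy logic).
#' @return a `trace_matrix`: data.table `individual`, `ancestor`,
#'   `raw_count`, `n_variant_sites`, `proportion`.
#' @export
trace_private_alleles <- function(gt, catalog, targets, pops = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  cat_dt <- as.data.table(catalog)
  bad <- setdiff(targets, gt$individuals)
  if (length(bad)) stop("unknown target individual(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(pops)) {
    anc <- attr(catalog, "ancestors")
    tpop <- pops$population[match(targets, pops$individual)]
    if (any(tpop %in% anc))
      stop("target(s) belong to an ancestral taxon: ",
           paste(targets[tpop %in% anc], collapse = ", "))
  }
  unknown_sites <- setdiff(cat_dt$site_id, gt$sites$site_id)
  if (length(unknown_sites))
    stop("catalogue refers to sites absent from the table (",
         length(unknown_sites), "); build and trace on the same site universe")
  sp <- split_calls(gt)
  a1 <- sp$a1[targets, , drop = FALSE]
  a2 <- sp$a2[targets, , drop = FALSE]
  n_sites <- rowSums(!is.na(a1))
  ancs <- unique(cat_dt$taxon)
  rows <- lapply(ancs, function(k) {
    pk <- cat_dt[cat_dt$taxon == k]
    if (nrow(pk)) {
      j <- match(pk$site_id, colnames(a1))
      am <- matrix(pk$allele, nrow = length(targets), ncol = nrow(pk),
                   byrow = TRUE)
      hitm <- (a1[, j, drop = FALSE] == am) | (a2[, j, drop = FALSE] == am)
      raw <- rowSums(hitm, na.rm = TRUE)
    } else raw <- rep(0L, length(targets))
    data.table(individual = targets, ancestor = k,
               raw_count = as.integer(raw),
               n_variant_sites = as.integer(n_sites),
               proportion = ifelse(n_sites > 0, raw / n_sites, NA_real_))
  })
  out <- if (length(rows)) rbindlist(rows) else
    data.table(individual = targets, ancestor = NA_character_,
               raw_count = 0L, n_variant_sites = as.integer(n_sites),
               proportion = ifelse(n_sites > 0, 0, NA_real_))
  structure(out, class = c("trace_matrix", class(out)))
}

#' Boxplot summary of traced proportions
#'
#' Per population-by-ancestor Tukey boxplot statistics of the traced
#' private-allele proportions, with the two-tier outlier convention:
#' quartiles by linear interpolation (R's default type 7), whiskers at
#' the most extreme observations within `Q +/- 1.5 IQR`, mild outliers
#' beyond 1.5 IQR (but within 3 IQR) and severe outliers beyond 3 IQR.
#'
#' @param trace a `trace_matrix`.
#' @param pops a [pop_map()] giving each individual's population.
#' @return a data.table `population`, `ancestor`, `n`, `q1`, `q2`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n_mild`, `n_severe`, plus list columns
#'   `mild` and `severe` with the outlying values.
#' @export
summarize_trace <- function(trace, pops) {
  dt <- as.data.table(trace)
  dt$population <- pops$population[match(dt$individual, pops$individual)]
  if (any(is.na(dt$population)))
    stop("traced individual(s) missing from popmap")
  dt <- dt[!is.na(dt$proportion)]
  dt[, {
    v <- proportion
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo_f <- q[1] - 1.5 * iqr; hi_f <- q[3] + 1.5 * iqr
    lo_s <- q[1] - 3.0 * iqr; hi_s <- q[3] + 3.0 * iqr
    inside <- v >= lo_f & v <= hi_f
    severe <- v < lo_s | v > hi_s
    mild <- !inside & !severe
    list(n = length(v), q1 = q[1], q2 = q[2], q3 = q[3],
         whisker_lo = if (any(inside)) min(v[inside]) else q[1],
         whisker_hi = if (any(inside)) max(v[inside]) else q[3],
         n_mild = sum(mild), n_severe = sum(severe),
         mild = list(sort(v[mild])), severe = list(sort(v[severe])))
  }, by = c("population", "ancestor")]
}
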