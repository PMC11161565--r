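# Brute-force oracles and fixture builders. Oracles are deliberately
# written as plain nested loops over the raw call strings, independent
# of the package's vectorized implementations.

# alleles of one call string, character(0) if missing
call_set <- function(x) {
  if (is.na(x)) character(0) else unique(strsplit(x, "/", fixed = TRUE)[[1]])
}

# random genotype table: n_ind x (n_loci * spl) sites over small allele pools
random_table <- function(n_ind, n_loci, spl = 1L, miss = 0.2,
                         inds = sprintf("I%02d", seq_len(n_ind))) {
  n_sites <- n_loci * spl
  calls <- matrix(NA_character_, n_ind, n_sites)
  for (s in seq_len(n_sites)) {
    pool <- sample(c("A", "C", "G", "T"), sample(2:3, 1))
    for (i in seq_len(n_ind)) {
      if (runif(1) < miss) next
      al <- sort(sample(pool, sample(1:2, 1)))
      calls[i, s] <- if (length(al) == 2L) paste(al, collapse = "/") else al
    }
  }
  locus <- rep(seq_len(n_loci), each = spl)
  col <- rep(seq_len(spl), n_loci) - 1L
  genotype_table(
    inds,
    data.frame(site_id = paste0("s", seq_len(n_sites)),
               locus_id = paste0("L", locus), column = col),
    calls
  )
}

# exhaustive private-allele catalogue
oracle_catalog <- function(gt, pops, ancestors, mode = "optimistic") {
  out <- list()
  for (k in ancestors) {
    inds_k <- pops$individual[pops$population == k]
    others <- unlist(lapply(setdiff(ancestors, k), function(o)
      pops$individual[pops$population == o]))
    for (s in gt$sites$site_id) {
      if (mode == "strict") {
        typed_all <- all(vapply(ancestors, function(o) {
          any(!is.na(gt$calls[pops$individual[pops$population == o], s]))
        }, logical(1)))
        if (!typed_all) next
      }
      mine <- unique(unlist(lapply(inds_k, function(i) call_set(gt$calls[i, s]))))
      theirs <- unique(unlist(lapply(others, function(i) call_set(gt$calls[i, s]))))
      for (a in setdiff(mine, theirs))
        out[[length(out) + 1L]] <- data.frame(taxon = k, site_id = s, allele = a)
    }
  }
  if (!length(out)) return(data.frame(taxon = character(), site_id = character(),
                                      allele = character()))
  do.call(rbind, out)
}

# exhaustive trace counts
oracle_trace <- function(gt, cat_df, targets) {
  out <- list()
  for (tg in targets) {
    n_sites <- sum(!is.na(gt$calls[tg, ]))
    for (k in unique(cat_df$taxon)) {
      pk <- cat_df[cat_df$taxon == k, , drop = FALSE]
      raw <- 0L
      for (r in seq_len(nrow(pk)))
        if (pk$allele[r] %in% call_set(gt$calls[tg, pk$site_id[r]]))
          raw <- raw + 1L
      out[[length(out) + 1L]] <- data.frame(
        individual = tg, ancestor = k, raw_count = raw,
        n_variant_sites = n_sites,
        proportion = if (n_sites > 0) raw / n_sites else NA_real_)
    }
  }
  do.call(rbind, out)
}

# site-by-site re-evaluation of the R / min-maf filters
oracle_filter_keep <- function(gt, pops, cfg) {
  keep <- logical(nrow(gt$sites))
  for (j in seq_along(keep)) {
    s <- gt$sites$site_id[j]
    cl <- gt$calls[, s]
    ok_r <- if (cfg$scope == "overall") {
      mean(!is.na(cl)) >= cfg$R
    } else {
      all(vapply(unique(pops$population), function(p) {
        ii <- pops$individual[pops$population == p]
        if (!length(ii)) TRUE else mean(!is.na(cl[ii])) >= cfg$R
      }, logical(1)))
    }
    copies <- unlist(lapply(cl, function(x) {
      a <- call_set(x)
      if (length(a) == 1L) c(a, a) else a
    }))
    maf <- if (length(copies)) 1 - max(table(copies)) / length(copies) else 0
    keep[j] <- ok_r && maf >= cfg$min_maf
  }
  keep
}

# canonical sort for catalogue comparison
cat_key <- function(x) sort(paste(x$taxon, x$site_id, x$allele))

# worked 3-site toy: ancestors A and B (one diploid each), derived D
toy_trace_fixture <- function() {
  calls <- rbind(
    A = c("A",   "C/T", "G"),
    B = c("A",   "C",   "A/G"),
    D = c("A",   "C/T", "G")
  )
  gt <- genotype_table(
    c("A", "B", "D"),
    data.frame(site_id = c("s1", "s2", "s3"),
               locus_id = c("L1", "L2", "L3"), column = 0L),
    calls
  )
  pops <- pop_map(c("A", "B", "D"), c("A", "B", "D"),
                  c("ancestral", "ancestral", "derived"))
  list(gt = gt, pops = pops)
}
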