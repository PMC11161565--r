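test_that("catalogue basics: shared alleles are never private", {
  gt <- genotype_table(
    c("a1", "b1"),
    data.frame(site_id = c("s1", "s2"), locus_id = c("L1", "L2"), column = 0L),
    rbind(a1 = c("T", "C/T"), b1 = c("T", "C"))
  )
  pops <- pop_map(c("a1", "b1"), c("A", "B"), c("ancestral", "ancestral"))
  catalog <- build_catalog(gt, pops, c("A", "B"))
  # T at s1 is shared; T at s2 is private to A
  expect_identical(cat_key(catalog), "A s2 T")
  expect_error(build_catalog(gt, pops, c("A", "Zz")), "absent")
  # empty catalogue warns but does not error
  gt2 <- genotype_table(c("a1", "b1"), gt$sites,
                        rbind(a1 = c("T", "C"), b1 = c("T", "C")))
  expect_message(c2 <- build_catalog(gt2, pops, c("A", "B")), "empty")
  expect_identical(nrow(c2), 0L)
})

test_that("optimistic vs strict missing-ancestor handling", {
  # ancestor B entirely missing at s1: optimistic admits A's allele,
  # strict skips the site
  gt <- genotype_table(
    c("a1", "b1"),
    data.frame(site_id = "s1", locus_id = "L1", column = 0L),
    rbind(a1 = "G", b1 = NA_character_)
  )
  pops <- pop_map(c("a1", "b1"), c("A", "B"), c("ancestral", "ancestral"))
  expect_identical(cat_key(build_catalog(gt, pops, c("A", "B"))), "A s1 G")
  expect_message(strict <- build_catalog(gt, pops, c("A", "B"), mode = "strict"))
  expect_identical(nrow(strict), 0L)
})

test_that("catalogue and trace match brute force on random instances", {
  # the deep acceptance run does 500 instances; keep a fast slice here
  for (rep in 1:60) {
    n_taxa <- sample(2:5, 1)
    n_anc <- n_taxa * 2L
    n_der <- sample(2:5, 1)
    gt <- random_table(n_anc + n_der, sample(5:20, 1), miss = 0.3)
    pops <- pop_map(gt$individuals,
                    c(rep(paste0("A", seq_len(n_taxa)), each = 2),
                      rep("D", n_der)),
                    c(rep("ancestral", n_anc), rep("derived", n_der)))
    ancs <- paste0("A", seq_len(n_taxa))
    mode <- sample(c("optimistic", "strict"), 1)
    got <- suppressMessages(build_catalog(gt, pops, ancs, mode = mode))
    want <- oracle_catalog(gt, pops, ancs, mode = mode)
    expect_identical(cat_key(got), cat_key(want), info = paste("rep", rep))
    if (nrow(got)) {
      targets <- pops$individual[pops$role == "derived"]
      tr <- trace_private_alleles(gt, got, targets)
      wtr <- oracle_trace(gt, as.data.frame(got), targets)
      m <- merge(as.data.frame(tr), wtr, by = c("individual", "ancestor"))
      expect_identical(m$raw_count.x, m$raw_count.y)
      expect_identical(m$n_variant_sites.x, m$n_variant_sites.y)
    }
  }
})

test_that("worked 3-site toy traces exactly", {
  fx <- toy_trace_fixture()
  catalog <- build_catalog(fx$gt, fx$pops, c("A", "B"))
  expect_identical(cat_key(catalog), c("A s2 T", "B s3 A"))
  tr <- trace_private_alleles(fx$gt, catalog, "D", fx$pops)
  trA <- tr[tr$ancestor == "A", ]
  trB <- tr[tr$ancestor == "B", ]
  expect_identical(trA$raw_count, 1L)
  expect_identical(trB$raw_count, 0L)
  expect_identical(trA$n_variant_sites, 3L)
  expect_equal(trA$proportion, 1 / 3)
  # ancestral individual as target contaminates privacy -> error
  expect_error(trace_private_alleles(fx$gt, catalog, "A", fx$pops),
               "ancestral")
})

test_that("trace handles empty catalogues and all-missing targets", {
  fx <- toy_trace_fixture()
  gt <- fx$gt
  gt$calls["D", ] <- NA_character_
  gt <- genotype_table(gt$individuals, gt$sites, gt$calls)
  catalog <- build_catalog(gt, fx$pops, c("A", "B"))
  tr <- trace_private_alleles(gt, catalog, "D")
  expect_true(all(is.na(tr$proportion)))
  expect_identical(unique(tr$n_variant_sites), 0L)

  empty <- suppressMessages(build_catalog(
    genotype_table(c("A", "B"), fx$gt$sites[1, ],
                   matrix(c("A", "A"), 2, 1, dimnames = list(c("A", "B"), "s1"))),
    fx$pops[fx$pops$role == "ancestral", ], c("A", "B")))
  tr0 <- trace_private_alleles(fx$gt, empty, "D")
  expect_true(all(tr0$proportion == 0 | is.na(tr0$proportion)))
})

test_that("extinct attribution excludes extant carriers and respects provenance", {
  gt <- genotype_table(
    c("u1", "c1", "p1", "p2"),
    data.frame(site_id = c("s1", "s2"), locus_id = c("L1", "L2"), column = 0L),
    rbind(u1 = c("A", "C"), c1 = c("A/T", "C/T"),
          p1 = c("A/G", "C/T"), p2 = c("G", "C"))
  )
  pops <- pop_map(c("u1", "c1", "p1", "p2"),
                  c("Ulm", "Can", "Rub", "Rub"),
                  c("ancestral", "ancestral", "proxy_polyploid", "proxy_polyploid"))
  ext <- attribute_extinct(gt, pops, "Rub", c("Ulm", "Can"))
  # G at s1 absent from both extant ancestors -> attributed;
  # T at s2 present in Can -> excluded; T at s1 present in Can -> excluded
  expect_identical(sort(paste(ext$site_id, ext$allele)), "s1 G")
  expect_identical(unique(ext$provenance), "extinct_attributed")
  expect_error(attribute_extinct(gt, pops, "Nope", c("Ulm")), "not in popmap")
  pops2 <- pop_map(c("u1", "c1", "p1", "p2"),
                   c("Ulm", "Can", "Rub", "Rub"),
                   c("ancestral", "ancestral", "derived", "derived"))
  expect_error(attribute_extinct(gt, pops2, "Rub", c("Ulm")), "proxy_polyploid")
})

test_that("ghost recall and null-attribution bounds hold in simulation", {
  # moderate size here; the full L = 2000 runs live in the acceptance suite
  d <- simulate_dataset(scenario_ghost(17))
  gtf <- filter_sites(d$table, d$popmap,
                      filter_config(R = 0.5, min_maf = 0.05, seed = 1))
  ext <- attribute_extinct(gtf, d$popmap, "Proxy", c("T1", "T2", "T3"))
  tp <- d$truth$private[d$truth$private$taxon == "ghost"]
  tp <- tp[tp$site_id %in% gtf$sites$site_id]
  pres <- patrace:::allele_presence(
    gtf, patrace:::pop_individuals(d$popmap, "Proxy"))
  reached <- mapply(function(s, a) pres[a, s], tp$site_id, tp$allele)
  reach <- tp[reached]
  expect_gt(nrow(reach), 10)
  recall <- mean(paste(reach$site_id, reach$allele) %in%
                   paste(ext$site_id, ext$allele))
  expect_gte(recall, 0.8)

  d0 <- simulate_dataset(scenario_ghost(17, ghost_on = FALSE))
  gtf0 <- filter_sites(d0$table, d0$popmap,
                       filter_config(R = 0.5, min_maf = 0.05, seed = 1))
  ext0 <- attribute_extinct(gtf0, d0$popmap, "Proxy", c("T1", "T2", "T3"))
  expect_lte(nrow(ext0), 10)   # sampling-miss false positives only
})

test_that("summarize_trace implements the 1.5/3.0 boxplot convention", {
  mk <- function(vals, pop = "P") {
    tr <- data.table::data.table(
      individual = paste0(pop, seq_along(vals)), ancestor = "A",
      raw_count = 1L, n_variant_sites = 10L, proportion = vals)
    pops <- pop_map(tr$individual, rep(pop, length(vals)),
                    rep("derived", length(vals)))
    summarize_trace(structure(tr, class = c("trace_matrix", class(tr))), pops)
  }
  # declared quartile method (linear interpolation, R type 7)
  s <- mk(1:9 / 10)
  expect_equal(c(s$q1, s$q2, s$q3), c(3, 5, 7) / 10)
  expect_identical(s$n_mild + s$n_severe, 0L)
  expect_equal(s$whisker_lo, 0.1)
  expect_equal(s$whisker_hi, 0.9)

  # single individual: degenerate box
  s1 <- mk(0.4)
  expect_equal(c(s1$q1, s1$q2, s1$q3), rep(0.4, 3))
  expect_identical(s1$n_mild + s1$n_severe, 0L)

  # injected outlier at Q3 + 4 IQR is severe; one at Q3 + 2 IQR is mild
  base <- c(1:9 / 10)
  q3 <- 0.7; iqr <- 0.4
  s2 <- mk(c(base, q3 + 4 * iqr))
  expect_identical(s2$n_severe, 1L)
  s3 <- mk(c(base, q3 + 2.6 * iqr))
  expect_identical(s3$n_mild, 1L)
  expect_identical(s3$n_severe, 0L)
  # quartile ordering invariant
  expect_true(all(s3$q1 <= s3$q2 & s3$q2 <= s3$q3))
})
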