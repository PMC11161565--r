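test_that("genotype_table enforces its invariants", {
  sites <- data.frame(site_id = c("s1", "s2"), locus_id = "L1", column = 0:1)
  calls <- matrix(c("A", "A/T", NA, "C"), 2, 2)
  gt <- genotype_table(c("I1", "I2"), sites, calls)
  expect_s3_class(gt, "genotype_table")
  expect_identical(dim(gt), c(2L, 2L))

  expect_error(genotype_table(c("I1", "I1"), sites, calls), "unique")
  expect_error(genotype_table(c("I1", "I2"),
    data.frame(site_id = c("s1", "s1"), locus_id = "L1", column = 0:1),
    calls), "site_id")
  expect_error(genotype_table(c("I1", "I2"),
    data.frame(site_id = c("s1", "s2"), locus_id = "L1", column = c(0, 0)),
    calls), "locus_id")
  # pos without chrom violates the coordinate invariant
  expect_error(genotype_table(c("I1", "I2"),
    data.frame(site_id = c("s1", "s2"), locus_id = "L1", column = 0:1,
               chrom = c(NA, NA), pos = c(5L, NA)), calls), "chrom")
  expect_error(genotype_table(c("I1", "I2"), sites,
    matrix(c("T/A", "A", "C", "C"), 2, 2)), "sorted")
})

test_that("VCF GT encodings map to pseudo-diploid calls", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t101\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.\t1/1",
    "chr1\t151\tv2\tC\tG,T\t.\tPASS\t.\tGT\t1/2\t0/0\t0|2",
    "chr1\t2050\tv3\tG\tGA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(gt <- read_vcf(f), "non-SNP")
  # indel record skipped, samples all retained
  expect_identical(gt$individuals, c("S1", "S2", "S3"))
  expect_identical(nrow(gt$sites), 2L)
  expect_identical(gt$calls["S1", "v1"], "A/T")
  expect_true(is.na(gt$calls["S2", "v1"]))
  expect_identical(gt$calls["S3", "v1"], "T")
  expect_identical(gt$calls["S1", "v2"], "G/T")   # multiallelic 1/2
  expect_identical(gt$calls["S3", "v2"], "C/T")   # phased separator
  # default binning: floor(pos/1000)
  expect_identical(unique(gt$sites$locus_id), "chr1:0")
  expect_identical(gt$sites$column, c(101L, 151L))
})

test_that("VCF write -> read round-trips a simulated table", {
  ds <- simulate_dataset(simulation_config(
    n_ancestors = 2, loci = 25, sites_per_locus = 2,
    derived = list(list(label = "D", n = 4, weights = c(T1 = 0.2))),
    seed = 42))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ds$table, f)
  gt2 <- read_vcf(f)
  expect_identical(gt2$calls, ds$table$calls)
  expect_identical(as.data.frame(gt2$sites), as.data.frame(ds$table$sites))
  expect_identical(gt2$individuals, ds$table$individuals)

  # a table without genomic coordinates survives via synthetic positions
  st <- ds$table$sites
  st$chrom <- NA_character_; st$pos <- NA_integer_
  gt_nc <- genotype_table(ds$table$individuals, st, ds$table$calls)
  write_vcf(gt_nc, f)
  gt3 <- read_vcf(f)
  expect_identical(gt3$calls, gt_nc$calls)
  expect_identical(as.data.frame(gt3$sites), as.data.frame(gt_nc$sites))
})

test_that("popmap reader parses roles and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S1\tAlp\tderived", "S2\tUlm\tancestral"), f)
  pm <- read_popmap(f)
  expect_identical(pm$population[pm$individual == "S1"], "Alp")
  expect_identical(pm$role[pm$individual == "S1"], "derived")

  writeLines(c("S1\tAlp\tderived", "S1\tUlm\tancestral"), f)
  expect_error(read_popmap(f), "duplicate")
  writeLines(c("S1\tAlp\tqueen"), f)
  expect_error(read_popmap(f), "role")
  # popmap individual absent from the table is a warning, not an error
  gt <- random_table(2, 2, inds = c("S1", "S2"))
  pm2 <- pop_map(c("S1", "S2", "S3"), c("A", "A", "B"),
                 c("derived", "derived", "derived"))
  expect_message(check_popmap <- patrace:::check_popmap(gt, pm2), "absent")
})

test_that("coords and borderline round-trip; degenerate inputs error", {
  co <- data.frame(individual = c("S1", "S2"),
                   lat = c(48.123456, -1.5), lon = c(17.654321, 9.999999))
  f <- withr::local_tempfile(fileext = ".csv")
  write_coords(co, f)
  co2 <- read_coords(f)
  expect_equal(co2$lat, co$lat, tolerance = 1e-12)  # 6 decimals preserved
  expect_equal(co2$lon, co$lon, tolerance = 1e-12)

  b <- data.frame(lat = c(48, 48.5), lon = c(8, 9))
  write_borderline(b, f)
  b2 <- read_borderline(f)
  expect_equal(b2$lat, b$lat)
  writeLines("lat,lon", f)
  expect_error(read_borderline(f), ">=1 point")
  writeLines(c("individual,lat,lon", "S1,91,0"), f)
  expect_error(read_coords(f), "latitude")
})

test_that("borderline GeoJSON LineString is parsed with lon/lat swapped", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(8, 48), c(9, 48.5)))
  ), auto_unbox = TRUE), f)
  b <- read_borderline(f)
  expect_equal(b$lat, c(48, 48.5))
  expect_equal(b$lon, c(8, 9))
})

test_that("sumstats TSV round-trips and tolerates dialect variation", {
  ds <- simulate_dataset(simulation_config(
    n_ancestors = 2, loci = 20,
    derived = list(list(label = "D", n = 3, weights = c(T1 = 0.2))),
    seed = 9))
  ss <- sumstats_from_table(ds$table, ds$popmap)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats_tsv(ss, f)
  ss2 <- read_sumstats_tsv(f)
  expect_equal(as.data.frame(ss2), as.data.frame(ss))

  # fixed-frequency toy: P = 1.0 parses as numeric 1
  writeLines(paste(
    c("Locus ID\tCol\tPop ID\tP Nuc\tQ Nuc\tP\tObs Het\tPrivate",
      "L1\t0\tPopA\tA\t-\t1.0\t0.0\t0",
      "L1\t0\tPopB\tA\tT\t0.5\t0.5\t1"), collapse = "\n"), f)
  ss3 <- read_sumstats_tsv(f)
  expect_identical(ss3$p[1], 1)
  # Windows line endings parse identically
  writeLines(paste(
    c("Locus ID\tCol\tPop ID\tP Nuc\tQ Nuc\tP\tObs Het\tPrivate",
      "L1\t0\tPopA\tA\t-\t1.0\t0.0\t0",
      "L1\t0\tPopB\tA\tT\t0.5\t0.5\t1"), collapse = "\r\n"), f, sep = "\r\n")
  expect_equal(as.data.frame(read_sumstats_tsv(f)), as.data.frame(ss3))
  # schema error names what is missing
  writeLines("Locus ID\tCol\tPop ID", f)
  expect_error(read_sumstats_tsv(f), "schema")
})

test_that("locus FASTA round-trips with the locus|individual header", {
  ds <- simulate_dataset(simulation_config(
    n_ancestors = 2, loci = 10, sites_per_locus = 2, seq_len = 30,
    derived = list(list(label = "D", n = 2, weights = c(T1 = 0.2))),
    seed = 4))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_locus_fasta(ds$seqs, f)
  sq <- read_locus_fasta(f)
  setkey_cols <- c("locus_id", "individual")
  o1 <- order(ds$seqs$locus_id, ds$seqs$individual)
  o2 <- order(sq$locus_id, sq$individual)
  expect_identical(sq$seq[o2], ds$seqs$seq[o1])
  expect_error(locus_seqset("L1", c("a", "b"), c("ACGT", "ACG")),
               "unequal|duplicate")
})

test_that("trace/diversity writers round-trip", {
  fx <- toy_trace_fixture()
  catalog <- build_catalog(fx$gt, fx$pops, c("A", "B"))
  tr <- trace_private_alleles(fx$gt, catalog, "D")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace_matrix(tr, f)
  tr2 <- read_trace_matrix(f)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(catalog, f2)
  expect_equal(cat_key(read_catalog(f2)), cat_key(catalog))
})
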