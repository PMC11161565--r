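#' Run the full analysis pipeline
#'
#' Chains simulate (optional) -> filter -> diversity -> per-individual
#' Hexp -> private-allele catalogue (plus extinct attribution when a
#' proxy population is present) -> trace -> boxplot summary -> mapping
#' affinity -> distance regression, writing every stage output as a
#' plain-text table plus a JSON manifest (input hashes, parameters,
#' package version, per-stage seeds) sufficient to reproduce
#' byte-identical results.
#'
#' The configuration is a named list (or a path to a JSON file with the
#' same structure):
#' \describe{
#' \item{out_dir}{output directory (created).}
#' \item{seed}{mandatory when simulation is requested; fans out to
#'   per-stage child seeds via [child_seed()].}
#' \item{simulate}{arguments for [simulation_config()] (minus the
#'   seed), or `NULL` to read inputs from files.}
#' \item{inputs}{when not simulating: paths `vcf`, `popmap`, `fasta`,
#'   `coords`, `borderline`.}
#' \item{filter}{arguments for [filter_config()].}
#' \item{regression}{`min_sites`, `exclude`, `mode`.}
#' \item{affinity}{`max_mismatch`.}
#' }
#'
#' @param config list or JSON path.
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`). On stage failure the partial outputs are
#'   retained with a `.partial` suffix and the error is re-thrown.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("could not create output directory ", out_dir)
  simulate <- !is.null(config$simulate)
  if (simulate && is.null(config$seed))
    stop("config validation error: simulation requested but no seed given")
  seed <- as.integer(config$seed %||% 1L)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    pa_log("stage ", name, " ...")
    r <- tryCatch(expr, error = function(e) {
      # retain partials under .partial names
      for (f in list.files(out_dir, full.names = TRUE))
        if (!grepl("\\.partial$", f)) file.rename(f, paste0(f, ".partial"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    pa_log(sprintf("stage %s done in %.2fs", name,
                   as.numeric(Sys.time() - ts, units = "secs")))
    r
  }
  params <- list()

  if (simulate) {
    sim_args <- config$simulate
    sim_args$seed <- child_seed(seed, "simulate-config")
    scfg <- do.call(simulation_config, sim_args)
    ds <- stage("simulate", simulate_dataset(scfg))
    gt <- ds$table; pops <- ds$popmap; seqs <- ds$seqs
    coords <- ds$coords; border <- ds$borderline
    stage("write-inputs", {
      write_vcf(gt, file.path(out_dir, "genotypes.vcf"))
      write_popmap(pops, file.path(out_dir, "popmap.tsv"))
      write_locus_fasta(seqs, file.path(out_dir, "loci.fasta"))
      write_coords(coords, file.path(out_dir, "coords.csv"))
      write_borderline(border, file.path(out_dir, "borderline.csv"))
      fwrite(ds$truth$individuals, file.path(out_dir, "truth_individuals.tsv"),
             sep = "\t", quote = FALSE, na = "NA")
      fwrite(ds$truth$private, file.path(out_dir, "truth_private.tsv"),
             sep = "\t", quote = FALSE)
    })
    params$simulate <- sim_args
  } else {
    inp <- config$inputs %||% stop("config needs inputs when not simulating")
    gt <- stage("read", read_vcf(inp$vcf))
    pops <- read_popmap(inp$popmap)
    seqs <- if (!is.null(inp$fasta)) read_locus_fasta(inp$fasta) else NULL
    coords <- if (!is.null(inp$coords)) read_coords(inp$coords) else NULL
    border <- if (!is.null(inp$borderline)) read_borderline(inp$borderline) else NULL
  }

  fargs <- config$filter %||% list()
  fargs$seed <- fargs$seed %||% child_seed(seed, "filter")
  fcfg <- do.call(filter_config, fargs)
  gtf <- stage("filter", filter_sites(gt, pops, fcfg))
  params$filter <- fargs

  div <- stage("diversity", population_diversity(gtf, pops))
  write_diversity_table(div, file.path(out_dir, "diversity.tsv"))
  ih <- stage("individual-hexp", individual_hexp(gtf))
  fwrite(ih, file.path(out_dir, "individual_hexp.tsv"), sep = "\t",
         quote = FALSE, na = "NA")

  ancestors <- config$ancestors %||%
    unique(pops$population[pops$role == "ancestral"])
  catalog <- stage("catalog", build_catalog(gtf, pops, ancestors))
  proxy_pops <- unique(pops$population[pops$role == "proxy_polyploid"])
  if (length(proxy_pops)) {
    ext <- stage("attribute-extinct",
                 attribute_extinct(gtf, pops, proxy_pops[1], ancestors))
    catalog <- combine_catalogs(catalog, ext)
  }
  write_catalog(catalog, file.path(out_dir, "catalog.tsv"))

  targets <- pops$individual[pops$role == "derived" &
                               pops$individual %in% gtf$individuals]
  tr <- stage("trace", trace_private_alleles(gtf, catalog, targets, pops))
  write_trace_matrix(tr, file.path(out_dir, "trace.tsv"))
  box <- stage("summarize", summarize_trace(tr, pops))
  fwrite(box[, !c("mild", "severe")], file.path(out_dir, "trace_boxplot.tsv"),
         sep = "\t", quote = FALSE)

  if (!is.null(seqs)) {
    refs <- lapply(ancestors, function(k) build_pseudoreference(seqs, pops, k))
    aff <- stage("affinity", mapping_affinity(
      seqs, refs, intersect(targets, unique(seqs$individual)),
      max_mismatch = config$affinity$max_mismatch %||% 1L))
    write_affinity(aff, file.path(out_dir, "affinity.tsv"))
  }

  if (!is.null(coords) && !is.null(border)) {
    dist <- stage("distance", distance_to_borderline(coords, border))
    fwrite(dist, file.path(out_dir, "distances.tsv"), sep = "\t", quote = FALSE)
    rargs <- config$regression %||% list()
    reg <- tryCatch(stage("geo-regress", {
      lapply(c("naive", "residual"), function(md) hexp_distance_regression(
        ih, dist, mode = md,
        min_sites = rargs$min_sites %||% 0L,
        exclude = rargs$exclude %||% character(0), pops = pops))
    }), error = function(e) {
      pa_log("regression skipped: ", conditionMessage(e), level = "WARN"); NULL
    })
    if (!is.null(reg)) {
      regdt <- rbindlist(lapply(reg, function(r)
        as.data.table(r[c("mode", "slope", "intercept", "r", "p", "n")])))
      fwrite(regdt, file.path(out_dir, "regression.tsv"), sep = "\t",
             quote = FALSE, na = "NA")
    }
  }

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "patrace",
    version = as.character(packageVersion("patrace")),
    seed = seed,
    stage_seeds = list(simulate = child_seed(seed, "simulate-config"),
                       filter = fargs$seed),
    params = params,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  )
  jsonlite::write_json(manifest[names(manifest) != "elapsed_s"],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pa_log(sprintf("pipeline complete in %.1fs -> %s", manifest$elapsed_s, out_dir))
  invisible(manifest)
}
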