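---
title: "Tracing ancestral private alleles through a polyploid hybrid complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing ancestral private alleles through a polyploid hybrid complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many polyploid plant complexes — brambles are a canonical case — arose by
hybridization among a handful of diploid progenitor species, sometimes
including lineages that are now extinct. Reduced-representation sequencing
(ddRADseq) of such a complex yields thousands of short loci genotyped with
a *diploid* caller, so each polyploid genotype is a **pseudo-diploid
call**: the unordered set of at most two observed alleles, with unknown
dosage. `patrace` implements the analysis layer for asking, from such
data: *which ancestors contributed to which derived individuals, and how
does diversity behave across a sexual/apomictic contact zone?*

The core statistic is deliberately simple. An allele is **private** to an
ancestral taxon if it is observed in that taxon and in none of the other
candidate ancestors. Counting how many catalogued private alleles of
ancestor *k* reappear in a derived individual — divided by the number of
variant sites recovered in that individual, to cancel coverage and
missing-data differences — gives a per-individual introgression proxy
that requires no phasing, no dosage, and no model fitting.

## Data model

* `genotype_table` — individuals x variant sites; each cell `"A"`,
  `"A/T"` or `NA`. Sites are grouped into RAD loci (`locus_id`,
  `column`), with optional genomic coordinates.
* `pop_map` — individual to (population, role). Roles: `ancestral`
  (defines the privacy universe), `derived` (tracing targets),
  `proxy_polyploid` (stand-in for an extinct ancestor).
* `locus_seqset` — per-locus, per-individual consensus sequences for the
  mapping-affinity module.

Dosage is *not* represented anywhere: every statistic uses presence /
absence plus diploid genotype frequencies, which is exactly what the
upstream diploid genotyper delivers for a tetraploid. Pentaploid or other
off-ploidy individuals are ordinary rows; their calls are whatever the
caller produced.

## The operations and their conventions

### Site filtering (`filter_sites`)

Three standard filters, applied in order: minimum proportion of genotyped
individuals `R` (cohort-wide or within every population); minimum
minor-allele frequency `min_maf`, with minor frequency defined as one
minus the frequency of the most common allele (pooled allele copies, a
heterozygote contributing one copy of each allele); optionally one
seeded-random surviving SNP per locus. Typical settings mirror common
practice: `R = 0.5` for population tables, `R = 0.7` with
`min_maf = 0.05` for per-individual heterozygosity.

### Diversity (`population_diversity`, `individual_hexp`)

Per population: `Hobs` (site-level heterozygote fraction averaged over
sites), `Hexp = 1 - sum(p^2)` averaged over sites, `FIS`, private-allele
count `PA` (privacy against *all* populations in the run, the convention
of population-genetics summary tables), and `PA` normalized by the mean
number of individuals per locus. Two deliberate choices:

* **No small-sample correction** on `Hexp`. The plain estimator is
  transparent and exactly testable by hand; the cost is a downward bias
  of order `1/(2N)` that shows up as a mild negative `FIS` offset in
  small samples.
* **`FIS` averaging order.** `(Hexp - Hobs)/Hexp` is averaged over
  polymorphic sites (`mean_of_ratios`, the default); the alternative
  `ratio_of_means` (one minus the ratio of site-averaged `Hobs` to
  site-averaged `Hexp`) is available as an argument. Neither is canonical
  for this pipeline's upstream tools; the default is fixed for
  reproducibility and both are exposed.

Per individual, `Hexp_ind` is the mean over the individual's non-missing
filtered sites of `1 - sum(p^2)` from its own two-allele call: 0.5 at a
heterozygous site, 0 otherwise — i.e. half the heterozygous fraction,
bounded by 0.5. `n_variant_sites`, the individual's recovered variant
sites, doubles as a coverage proxy.

### Private-allele catalogue and tracing (`build_catalog`,
`attribute_extinct`, `trace_private_alleles`)

The **privacy universe is the listed ancestral taxa only**. Derived and
proxy populations never veto privacy: derived taxa are *expected* to
carry ancestral alleles, and letting them veto would empty the catalogue.
An ancestor entirely missing at a site cannot be excluded as a carrier;
by default such sites still admit privates for the other taxa
(`mode = "optimistic"`), and a `strict` mode skips any site not typed in
every ancestor. Both behaviors are tested; the choice matters only at
sites with pathological missingness.

**Extinct-ancestor attribution**: alleles present in a designated proxy
polyploid population and absent from every extant ancestor are attributed
to a ghost lineage and traced as a separate catalogue entry
(provenance `extinct_attributed`). These alleles may legitimately overlap
derived populations' alleles — only extant ancestors exclude. False
positives at this step are ancestor-sampling misses (an allele the
ancestor carries at low frequency but no sampled individual shows); with
ten diploids per ancestor their expected number is of order one among
thousands of sites.

**Tracing** counts each catalogue (site, allele) pair at most once per
individual — dosage being unknowable — and normalizes by the individual's
non-missing site count in the filtered table. The per-individual
denominator is the point: raw counts scale with data recovery, the
proportion does not.

Population summaries of traced proportions use Tukey boxplot statistics
(type-7 linear-interpolation quartiles) with the two-tier outlier
convention: mild beyond 1.5 IQR, severe beyond 3.0 IQR.

### Pseudoreference mapping affinity (`build_pseudoreference`,
`mapping_affinity`)

A desk-scale, deterministic stand-in for mapping a derived individual's
reads against per-ancestor references built from mixed per-individual
locus consensus sequences. A target's locus "maps" to a taxon if its
consensus is within `max_mismatch` (default 1, mirroring a
maximum-one-difference aligner) of *any* of the taxon's entries for that
locus, with `N` matching anything. The raw fraction of mapped loci is
centered by the within-individual mean across taxa, which removes
inter-individual data-quality differences exactly (row means of the
centered matrix are zero). Indels and soft-clipping are out of model;
the proxy preserves the statistic's logic, not read-level alignment
semantics.

### Contact-zone regression (`distance_to_borderline`,
`hexp_distance_regression`)

Distance uses the haversine great-circle formula (Earth radius 6371 km)
to the *nearest vertex* of the ordered borderline point list — the
"distance to nearest hub" convention of desktop GIS tools — with
perpendicular segment projection available as an option (never larger
than the hub distance).

Individual `Hexp` is confounded by coverage: low-coverage individuals
lose heterozygous calls and recover fewer sites, so `Hexp_ind` and
`n_variant_sites` correlate. The `residual` estimator therefore first
regresses `Hexp_ind` on `n_variant_sites` and then regresses the
residuals on distance. Its known biases, derived in closed form and
reproduced by the generator below: the heterozygote-dropout factor
multiplies the true slope by (1 - mean dropout), and any correlation
rho between coverage and distance removes a further rho^2 share of the
signal in the first stage. At the generator's default confound
(mean dropout ~ 0.14, rho^2 ~ 0.08) the residual estimator recovers
about 80% of the generating slope while the naive estimator is attenuated
to roughly half — the qualitative contrast the residual correction is
for. The default `min_sites = 6000` filter reflects typical practice of
excluding poorly recovered individuals entirely.

## The synthetic world (`simulate_dataset`)

The generator is first-class, tested code. It emulates the *statistical
structure* the analyses assume, not sequence evolution:

1. Per site, two base alleles; per source (each extant taxon, optional
   ghost, and a base pool shared by all derived individuals), allele
   frequencies from a symmetric Dirichlet. With probability `pi_k` a
   taxon-unique third allele at frequency 0.2-0.8 replaces one base
   allele in taxon *k* only; injected privates are disjoint across taxa
   by construction.
2. Ancestral diploids draw two copies from their taxon; derived
   tetraploids draw four copies with per-copy source given by the
   individual's ancestry weights `w`, then collapse to the two most
   frequent distinct alleles (seeded tie-break) — the pseudo-diploid
   call a diploid caller would report.
3. Clonal (apomictic) populations copy a founder genotype per clone
   group with per-site alteration probability `epsilon <= 0.01`.
4. The ghost taxon emits no diploid samples; it reaches the data only
   through derived populations' weights and a proxy polyploid population
   (default half ghost, half the first extant taxon).
5. Missingness is uniform per individual in `missing_rate_range`.
   The optional coverage confound ties a latent per-individual coverage
   to distance from the contact line and converts low coverage into both
   missingness and heterozygote dropout.
6. Locus sequences are the shared base sequence with one allele of the
   individual's call substituted at each variant column (`N` when
   missing). Geography is a straight west-east contact line with
   Gaussian population clouds at configurable distances — only distances
   matter downstream.

There is no drift, no coalescent, no linkage, no sequencing-error model:
the traced statistics depend only on allele-sharing patterns, and a
frequency-sampling model creates those patterns with trivial runtime.
A green test on this world therefore establishes correctness of the
*computations* and recoverability of the *designed* signals; it says
nothing about robustness to demographic history, allelic dropout
structure, or paralogy, which real RADseq data add on top.

Default magnitudes, chosen once as field-plausible: ancestry weights for
a donor taxon in the 0-0.2 range (the interesting regime for detecting
backcross-level introgression); private-allele supply `pi = 0.05`;
10 diploids per ancestral taxon; 5-15% baseline missingness; an imposed
heterozygosity decline of 5e-4 per km over a 10-90 km transect for
gradient-recovery tests. The canonical configurations live in
`scenario_*()` and are shared verbatim by the test suite and
`scripts/acceptance.R`. Monte-Carlo sizes within them (e.g. 400
individuals in the normalization scenario, 800 loci and three pooled
replicates for the affinity-concordance statistic) were set so that the
sampling error of the measured property is small against its acceptance
band — resolution of the measurement, not tuning of the world.

## Numerical conventions

* Quartiles: R type 7 (linear interpolation), fixed.
* Haversine with `asin(pmin(1, sqrt(a)))` to guard rounding at antipodal
  arguments.
* All randomness flows from one integer seed through `child_seed(seed,
  stage)` — a documented integer hash kept below 2^31 — so stages can be
  rerun independently and a `run_pipeline` run is byte-identical under a
  fixed seed (the manifest records md5 sums of every output).
* Degenerate inputs are defined, not accidental: empty filter results
  are logged and returned empty; an individual with no recovered sites
  gets `NA` proportions and `NA` `Hexp_ind`; a population with no
  individuals yields an `N = 0` record with `NA` statistics; a
  monomorphic population has `FIS = NA`.

## Known limitations

* Privacy is sensitive to ancestor sampling depth; the optimistic
  missing-site rule trades a small false-positive rate for coverage
  robustness (the strict mode trades the other way).
* The affinity proxy operates on fixed-length loci; indels and
  mapping-quality effects are out of model.
* The pseudo-diploid collapse discards real dosage signal that a
  polyploid-aware caller would retain; this mirrors the upstream
  pipeline rather than improving on it.
* `Hexp` carries the uncorrected small-sample bias noted above; compare
  populations of similar size, or equalize samples, as the upstream
  analyses do.
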