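# patrace

Private-allele tracing and diversity statistics for polyploid hybrid
complexes genotyped at RADseq-style loci.

## What problem this solves

Polyploid plant complexes (apomictic brambles are the motivating case)
typically arose by hybridization among a few diploid progenitors — some
of which may be extinct. Genotyping such a complex with a diploid caller
yields *pseudo-diploid* calls: at each variant site, the unordered set of
at most two observed alleles, dosage unknown. `patrace` turns those calls
into introgression and diversity inference:

* **Private-allele catalogues.** An allele is private to ancestral taxon
  *k* if it occurs in *k* and in no other candidate ancestor. Alleles of
  a designated *proxy polyploid* population absent from **all** extant
  ancestors are attributed to an extinct ("ghost") ancestor and traced
  separately.
* **Tracing.** For each derived individual and ancestor, the number of
  catalogued private alleles observed, divided by the individual's
  recovered variant sites — a per-individual normalization that cancels
  unequal coverage and missing data. Population summaries use Tukey
  boxplots with mild (1.5 IQR) and severe (3.0 IQR) outlier tiers.
* **Diversity.** Per population: N, individuals per locus, Hobs,
  Hexp = 1 − Σp², F_IS, private-allele counts (raw and per-N). Per
  individual: Hexp (= half the heterozygous fraction) and recovered
  variant sites.
* **Pseudoreference affinity.** A deterministic, desk-scale analogue of
  read mapping against per-ancestor references: a locus "maps" to a taxon
  if it is within `max_mismatch` (default 1) of any of the taxon's
  consensus entries; fractions are centered within individuals.
* **Contact-zone regression.** Haversine distance to the nearest vertex
  of a sexual/apomict borderline, then regression of individual Hexp on
  distance — naive, and with residuals from a first-stage regression on
  recovered variant sites to remove the coverage confound.
* **Synthetic data with ground truth.** A fully seeded generator
  (ancestral taxa with private-allele supply, derived tetraploids with
  ancestry weights, clonal apomict groups, a ghost ancestor reachable
  only through a proxy population, coverage-dependent missingness, a
  geographic contact line) used for parameter-recovery validation.

Formats: VCF (read/write), Stacks-style `sumstats` TSV, popmap TSV,
FASTA locus consensus (`>locusID|individualID`), coordinates CSV,
borderline CSV/GeoJSON.

## Worked example

```r
library(patrace)

cfg <- simulation_config(
  n_ancestors = 3, loci = 1000, private_rate = 0.05, ancestral_n = 10,
  derived = list(
    list(label = "Alp", n = 8, weights = c(T1 = 0.15)),
    list(label = "Apo", n = 8, weights = c(T2 = 0.1), clonal = TRUE,
         clone_groups = 2)),
  seed = 42)
ds  <- simulate_dataset(cfg)
gtf <- filter_sites(ds$table, ds$popmap,
                    filter_config(R = 0.5, min_maf = 0.05, seed = 42))
population_diversity(gtf, ds$popmap)
```

```
   population     N N_per_locus_mean N_per_locus_sd  Hobs  Hexp     FIS    PA PA_per_N
1:         T1    10             9.11          0.909 0.332 0.313 -0.0632    10     1.10
2:         T2    10             9.05          0.921 0.338 0.319 -0.0608    28     3.09
3:         T3    10             8.95          0.956 0.340 0.323 -0.0553    46     5.14
4:        Alp     8             7.22          0.841 0.674 0.422 -0.5484     0     0.00
5:        Apo     8             7.30          0.809 0.669 0.382 -0.7077     0     0.00
```

The tetraploids (Alp, Apo) show the expected fixed-heterozygosity excess
(Hobs well above Hexp, strongly negative F_IS — extreme in the clonal
Apo); the ancestral diploids sit near Hardy–Weinberg.

```r
catalog <- build_catalog(gtf, ds$popmap, c("T1", "T2", "T3"))
targets <- ds$popmap$individual[ds$popmap$role == "derived"]
tr  <- trace_private_alleles(gtf, catalog, targets, ds$popmap)
summarize_trace(tr, ds$popmap)
```

```
   population ancestor     n     q1     q2     q3 whisker_lo whisker_hi
1:        Alp       T1     8 0.0229 0.0244 0.0267     0.0197     0.0303
2:        Apo       T1     8 0.0089 0.0113 0.0133     0.0085     0.0143
3:        Alp       T2     8 0.0092 0.0101 0.0109     0.0067     0.0112
4:        Apo       T2     8 0.0183 0.0199 0.0205     0.0151     0.0213
5:        Alp       T3     8 0.0086 0.0089 0.0092     0.0081     0.0097
6:        Apo       T3     8 0.0094 0.0100 0.0105     0.0085     0.0110
```

Alp was simulated with 15% T1 ancestry and Apo with 10% T2 ancestry:
traced proportions recover exactly that contrast (Alp's T1 median 0.024
vs Apo's 0.011; Apo's T2 median 0.020 vs Alp's 0.010), while the
uninvolved ancestor T3 is flat across both.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","patrace.R",package="patrace"))') \
  run-all --config config.json
```

Subcommands: `simulate`, `filter`, `diversity`, `catalog`, `trace`,
`affinity`, `geo-regress`, `run-all`. A `run-all` run writes every stage
table plus a `manifest.json` (parameters, per-stage seeds, md5 of every
output); reruns with the same config and seed are byte-identical.

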