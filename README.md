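# gyraseq

Single-nucleotide mapping of DNA gyrase cleavage sites (GCSs) from
strand-aware fragment-end coverage.

## The problem

DNA gyrase, the bacterial type II topoisomerase, cleaves both DNA strands
during catalysis, leaving a 4-bp 5'-overhang covalently attached to the
enzyme. Gyrase poisons (ciprofloxacin, oxolinic acid, microcin B17) trap this
covalent cleavage intermediate. After immunoprecipitation of trapped
complexes and single-strand sequencing, only the free DNA chains — whose
3' ends point into the catalytic site — are sequenced. The footprint of one
cleavage event is therefore a pair of sharp 3'-end "walls" separated by a
4-bp coverage gap: forward-aligned fragments pile their 3' ends on the left
wall `i`, reverse-aligned fragments on the right wall `i + 5`, and the
overhang `[p0, p0+4)` with `p0 = i + 1` receives no 3' ends at all.

`gyraseq` is for microbial genomicists who have such data (or want to
prototype the analysis before generating it): it calls cleavage sites at
single-nucleotide resolution, characterizes the long degenerate gyrase
binding motif, and tests how sites distribute over genomic features.

## The method

For each experiment a **quartet** of samples is analyzed: poison + IP
(`+A+IP`), poison without IP, untreated + IP, and untreated without IP.
Calling proceeds in two normalization steps and one test:

1. **Library scaling** — every per-position 3'-end count (N3E) track is
   divided by its own total and multiplied by the smallest total in the
   quartet.
2. **Copy-number correction** — each IP track is divided by its matching
   mock track smoothed with a 200-kb sliding window, removing the ori–ter
   replication gradient.
3. **Paired-wall test** — position `i` is a site when the treated signal at
   both `i` and `i + 5` exceeds the untreated-IP control by the
   Audic–Claverie count test, `p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1+n2/n1)^(x+y+1))`,
   upper tail below `alpha = 0.0025` at each wall. Sites found in at least
   two of three replicates are kept; site strength is the mean height of the
   two walls.

The motif toolkit aligns 130-bp windows (offsets −63..66) under called
sites, builds a position probability matrix and its GC% track, masks the
drug-biased overhang columns (offsets 0–3) with the genome composition when
combining conditions, converts to a log2-odds PWM and scans sequences on
both strands (per-position score = strand maximum). A sinusoid grid fit over
the flanks recovers the ~10.75-bp GC periodicity that reflects DNA wrapping
around the GyrA C-terminal domains. The statistics module provides exact
binomial interval enrichment, a 10-bin genome scan with a
0.0005/0.9995-quantile binomial envelope, Fisher and conditional-Poisson
exact tests, strand-aware transcription-unit compartment association and a
sign-type test for strength changes between conditions. A simulator
generates genomes with planted, weighted sites and full quartets carrying
the wall-pinned signal structure, for end-to-end validation with known
truth.

## Worked example

```r
library(gyraseq)
set.seed(1)
L <- 50000
sites <- data.frame(p0 = sort(sample(200:(L - 1000), 10)),
                    weight = 10^runif(10, 0, 1))
cfg <- sim_config(L, planted_sites = sites, n_fragments = 5e4,
                  signal_fraction = 0.4)
g <- simulate_genome(cfg)
calls <- lapply(1:3, function(r)
  call_quartet(simulate_quartet(g$genome, cfg, replicate = r)$quartet))
gcs <- merge_replicates(calls, min_support = 2)
head(gcs, 3)
#>      p0 left_wall right_wall n3e_strength        p_left       p_right replicate_support
#> 1  4249      4248       4253    1863.4876  0.000000e+00  0.000000e+00                 3
#> 2  8428      8427       8432     538.6612 9.503266e-127 1.534735e-123                 3
#> 3 11770     11769      11774     742.5001 1.153330e-168 1.347731e-173                 3
```

All 10 planted sites are recovered at their exact coordinates, every one
with the hallmark 4-bp gap (`right_wall - left_wall - 1`). `n3e_strength`
is the normalized mean wall height (relative trapping frequency); the two
p-values are the per-wall Audic–Claverie tails. Downstream:

```r
enr <- binomial_enrichment(gcs$p0,
                           interval_set(data.frame(start = 0, end = 10000),
                                        name = "first10kb"), L)
enr
#> enrichment in first10kb: 2/10 observed, 2.00 expected (fold 1.000)
#>   p_over = 0.624, p_under = 0.678, two-sided = 1
```

Sites are uniform here, as planted. The same pipeline is scriptable through
`run_stage("simulate"|"profile"|"call"|"motif"|"scan"|"stats", ...)` or the
command line (`gyraseq_main()`), each run writing a `manifest.json` with the
config snapshot, input checksums and seed.

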