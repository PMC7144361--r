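# symbiovar

Organelle genetic variation and RNA-editing correspondence in coral
symbionts.

## The problem

Corals are holobionts: whole-genome shotgun (WGS) reads from a coral branch
mix host DNA with that of its symbiotic dinoflagellates (Symbiodiniaceae).
The symbiont's organelle genomes — three mitochondrial genes (*cox1*,
*cox3*, *cob*) and twelve single-gene plastid minicircles (*psbA* …
*atpB*) — are high-copy, so per-sample consensus ("representative")
sequences of these 15 genes can be extracted from holobiont reads alone.
Two questions follow:

1. **Population structure** — do symbiont organelle phylogenies separate
   host locality groups (Okinawa OK, Kerama KR, Yaeyama-North YN,
   Yaeyama-South YS)?
2. **RNA editing** — dinoflagellate organelle transcripts are heavily
   edited; do SNP sites among samples coincide with known editing sites,
   as expected if gain/loss of editing drives polymorphism?

`symbiovar` implements the full analysis for both questions, plus a
synthetic holobiont cohort generator with known ground truth so that every
stage is testable offline.

## The method

For sample *s* and gene *g*, reads are mapped by a k-mer seed-and-extend
mapper (unique-best placement, mismatch ceiling `ceil(0.04 L)`), giving a
per-site base-count pileup. The representative sequence takes the dominant
base per site (`N` below the depth floor); samples with compartment-wide
covered fraction < 0.90 are removed per compartment. A site is a SNP iff
≥ 2 distinct bases occur among retained samples (`N` is missing data, never
an allele). With an editing catalogue *E(g)* of known edited positions,
the correspondence count per gene is

```
corr(g) = | SNP(g) ∩ E(g) |
```

reported both as a share of SNP sites and of editing sites. Each SNP site
is classified nonsynonymous/synonymous by substituting every alternate
allele into the consensus-major codon (any amino-acid change ⇒ ns).
Population structure uses p-distances over mutually non-`N` sites of the
concatenated genes, neighbor-joining, and column-bootstrap supports.
ITS2 reads are typed by best local-alignment score (ties across types ⇒
unassigned); a sample is "typed" with ≥ 2 assigned reads.

## Worked example

A reduced synthetic cohort (36 samples, full 15-gene set, 2
coverage-starved samples, diverged YN pool), analyzed end to end:

```r
library(symbiovar)

cfg <- cohort_config(
  n_samples_per_group = c(OK = 12, KR = 8, YN = 8, YS = 8),
  mt_coverage = 20, pt_coverage = 9,
  n_low_coverage_samples = 2, n_its2_typed_samples = 12, seed = 2026)
cohort   <- synthesize_cohort(cfg)
analysis <- analyze_cohort(cohort)
glance(analysis)
#>   compartment analyzed_sites n_snp snp_pct n_prnae prnae_pct n_correspondence
#> 1 mt                    3288   153     4.7      71       2.2               63
#> 2 pt                   13959  1270     9.1     404       2.9               75
```

Reading: the plastid compartment is more polymorphic (9.1% of 13,959 sites)
than the mitochondrial one (4.7% of 3,288), yet the SNP/editing
correspondence is far stronger in mt — 63 of 71 catalogued mt editing sites
are SNPs (89%) versus 75 of 404 in pt (19%) — the asymmetry the analysis is
designed to expose. Population structure from the concatenated mt genes:

```r
pop <- popstruct_compartment(analysis, cohort$references, cohort$samples,
                             compartment = "mt", seed = 1)
tidy(pop$clusters)
#>   locality_group n_samples_in_tree clade_size clade_support
#> 1 OK                            12          1            NA
#> 2 KR                             6          1            NA
#> 3 YN                             8          8            92
#> 4 YS                             8          1            NA
```

Only the planted divergent group (YN) forms a supported exclusive clade
(all 8 samples, 92% bootstrap); the other groups stay interleaved — the
same qualitative picture as for the real holobiont populations the default
configuration emulates. (KR shows 6 of 8 samples because the two
coverage-starved samples were removed by QC.) ITS2 typing:

```r
its2 <- assign_its2_types(cohort$its2_reads, cohort$its2_refs)
count_typed_samples(its2)
#> [1] 12
```

`autoplot(analysis$report)` draws the per-gene SNP/editing percentage
panel, `plot_correspondence(analysis$report)` the compartment
correspondence shares.

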