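---
title: "Methods: organelle genetic variation and RNA-editing correspondence in coral symbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle genetic variation and RNA-editing correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiovar)
```

## The problem

Reef corals host symbiotic dinoflagellates (family Symbiodiniaceae) whose
population structure is hard to read directly from holobiont whole-genome
shotgun (WGS) data: the sequenced DNA is a mixture of host and symbiont
genomes. The symbiont's organelle genomes — three mitochondrial (mt)
protein-coding genes (*cox1*, *cox3*, *cob*) and twelve plastid (pt)
minicircle genes (*psbA* … *atpB*) — are high-copy, so even at modest
holobiont coverage their genes attract enough reads to call per-sample gene
sequences. Dinoflagellate organelle transcripts are also heavily
RNA-edited, and a gain or loss of an editing site in a lineage shows up in
genomic data as a polymorphism whose two alleles are exactly the pre- and
post-edit base. `symbiovar` implements the complete analysis chain that
quantifies this SNP/editing correspondence and reads population structure
from the same consensus sequences, plus a synthetic cohort generator that
lets every stage be validated against known ground truth.

## Pipeline model

For each sample, reads are mapped to the reference gene set by a k-mer
seed-and-extend mapper (`build_index()`, `map_reads()`): up to three
non-overlapping 21-mers per read are probed against an exact index of both
reference strands, each hit is extended ungapped over the full read, and the
placement with fewest mismatches wins. A read is unmapped when its best
placement exceeds `ceiling(0.04 * read_length)` mismatches or when two
distinct placements tie ("unique best"); the tie rule keeps paralog
cross-talk and palindromic artifacts out of the pileups. Ungapped extension
is sufficient because the downstream analysis is strictly site-wise on fixed
reference coordinates and the generator plants no indels. This mapper is a
deliberate stand-in for a production aligner, not a reproduction of one;
equivalently, pre-mapped alignments can enter through `ingest_sam()`, which
honors CIGAR operations `M/=/X/I/D/S` and skips unmapped and secondary
records. Multi-mapped handling is our policy choice (discard on tie), since
the upstream study does not state one.

Placements accumulate into a per-gene `length x 5` base-count pileup
(`A,C,G,T,other`), with reverse-strand reads complemented before counting —
references are single-stranded coding sequences, so the pileup is
strand-collapsed.

The **representative sequence** of a gene in a sample
(`call_representative()`) takes the dominant (most frequent) base at each
site with depth at least `min_depth` (default 1). Count ties break in favor
of the reference base when it is among the tied set — minimizing spurious
SNPs — else to the lexicographically smallest base, a deterministic and
documented convention. Sites below the depth floor are written `N` and stay
`N`: missing data must never masquerade as the reference allele.

**QC rule** (`qc_filter()`): a sample is retained for a compartment iff the
fraction of that compartment's coding sites with depth ≥ 1 reaches 0.90. The
threshold operationalizes "low coverage of protein-coding sequences"; at the
default study conditions retained samples sit near 0.97–1.00 and starved
samples near 0.36–0.64, so the rule is insensitive to the exact threshold
over a wide range. Filtering is per compartment — a sample can legitimately
pass mt and fail pt.

**SNP sites** (`detect_snp_sites()`): among the retained representative
sequences of a gene (all in reference coordinates by construction, so no
multiple sequence alignment stage is needed), a site is a SNP iff at least
two distinct bases from `A/C/G/T` occur; `N` never creates a SNP. The
denominator of all percentages is the full gene length, including sites that
are `N` everywhere. Each SNP site is then matched against the RNA-editing
catalogue (`correspond_with_editing()`): a "correspondence" is a SNP at a
catalogued position, and the gain/loss signature — both the genomic and the
edited base among the observed alleles — is recorded separately.

**ns/ss classification** (`classify_ns_ss()`): the codon around a SNP site
is built from the cohort consensus-major base at the other two positions,
and every alternate allele is substituted in turn; if any substitution
changes the amino acid the site counts as nonsynonymous (a codon site
showing both kinds counts as ns). Translation uses NCBI genetic-code table 1
by default, configurable per gene, since no dedicated dinoflagellate
organelle table is established. Sites in a trailing partial codon are
excluded with a warning. This direct codon-comparison rule implements the
stated ns-wins convention; it is not a reimplementation of any specific
counting software.

**Population structure** (`popstruct_compartment()`): per-compartment
representative sequences are concatenated in fixed gene order, pairwise
p-distances are computed over mutually non-`N` sites (via `ape::dist.dna`,
raw model, pairwise deletion), and a neighbor-joining tree is built
(`ape::nj`, negative branches clamped to 0). Support comes from resampling
alignment columns with replacement, one NJ tree per replicate (default
100), counting each original bipartition. NJ on p-distances is the package's
documented stand-in for maximum-likelihood inference: the validation target
is recovery of planted population structure, not reproduction of any
model-based tree of real data. Trees are left unrooted (no outgroup is
defined for these data); `assess_clusters()` therefore reads both sides of
every internal edge as candidate clades when looking for the largest
single-group clade with support ≥ 70%.

**ITS2 typing** (`assign_its2_types()`): each read is scored against every
ITS2 reference by best local alignment (match +2, mismatch −3, gap of length
L costing 5 + 2L, both strands); the highest-scoring type is assigned when
the score reaches 100 (≈ 50 matched bases). The raw-score threshold is a
stand-in for a BLAST E-value cutoff — E-values need database statistics out
of scope here. Exact score ties across different types leave a read
unassigned (conservative). A sample counts as "typed"
(`count_typed_samples()`) when at least `min_reads = 2` of its reads are
assigned, reading "more than one read" strictly; set `min_reads = 1` for
the laxer reading.

## The synthetic cohort generator

`synthesize_cohort()` generates, under one seed: random reference genes at
the published lengths (3,288 mt + 13,959 pt coding sites); an editing
catalogue with per-compartment densities 72/3,288 (mt) and 406/13,959 (pt);
155 samples in four locality groups (OK = 60, KR = 35, YN = 30, YS = 30 by
default — the study reports 155 total without per-group counts we can
reuse, so the split is the package's choice); population haplotypes; ~35×
mt / ~9× pt paired-end 100 bp reads with substitution errors at 0.001; and
ITS2 references plus planted ITS2 reads.

The haplotype model makes each site polymorphic independently with
probability 68/72 (mt) or 81/406 (pt) if it is an editing site, else
117/3,216 (mt) or 1,179/13,553 (pt) — the conditional rates implied by the
published per-gene counts — so the expected SNP totals, editing
correspondences, and their compartment asymmetry match the study conditions
by construction. At a polymorphic editing site the two alleles are the
genomic and the edited base; elsewhere the alternate is a random other base.

Allele frequencies: a fraction (15%) of polymorphic sites discriminate the
diverged locality group (default YN), with alternate-allele frequency 0.95
inside the group and 0.02 outside — this emulates the "long branch"
southern-symbiont pool and is the free, uncalibrated divergence parameter
of the generator. All other sites draw one cohort-wide minor-allele
frequency from Beta(0.8, 4) clamped to [0.02, 0.5], a spectrum skewed
toward rare variants as in neutral expectations. A uniform MAF spectrum was
rejected during development: making every SNP common gives diverged samples
~3.4% plastid divergence from the reference, which collides with the
mapper's 4% mismatch ceiling and erodes their covered fraction — an
internal inconsistency with the study condition that only the five
deliberately coverage-starved samples fail QC. Every polymorphic site is
forced to segregate in at least two samples per allele (cohorts ≥ 4), so
planted truth is always observable in principle.

Reads: fragments of fixed length `2 * read_length + 50` (no length jitter —
mates are mapped independently, so insert realism is irrelevant) are placed
uniformly with overhang past the gene ends allowed and reads clipped to the
gene. Clipping mimics reads extending into flanking genomic context and
keeps realized depth uniform across the CDS, including the ends; clipped
reads under 30 bp are dropped. Five samples are coverage-starved by a
factor of 0.02: the residual mt coverage (0.7×) leaves an expected covered
fraction ~0.50, far enough below the 0.90 threshold that the QC rule
triggers for every seed (a 0.05 factor leaves starved mt coverage at 1.75×,
whose covered fraction ~0.83 is close enough to the boundary that
fragment-occupancy variance lets an occasional starved sample slip
through).

ITS2: four types (C1, C3, C15, D1) at 8% pairwise divergence from a common
ancestor; 51 samples receive 2–8 reads from one type each, with
Durusdinium-like (`D*`) types planted only in Yaeyama (YN/YS) samples,
mirroring the study's observation.

What the generator does **not** emulate: indel polymorphism, minicircle
non-coding cores, quality-score-dependent error models, nuclear/host decoy
reads, linkage between sites, and within-sample symbiont mixtures
(heteroplasmy). Passing tests therefore demonstrate correctness of the
analysis operations under the stated statistical structure, not robustness
to hybrid reads or mixed infections in real holobiont data — the dominant-
base consensus explicitly collapses any mixture.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; TSV and report output are
1-based. Report percentages round half-up to one decimal (display
convention); all percentages are recomputable from the integer columns, and
one published per-gene percentage known to be a misprint is deliberately
recomputed from counts rather than copied. p-distance over zero comparable
sites returns 0 with a warning. NJ input must be finite; ties in consensus
calling and type assignment resolve as described above. `qc_filter()` stops
with advice rather than returning an empty cohort when every sample fails a
compartment.

## Validation design and problem sizes

Every operation is tested against an independent oracle where one exists:
pileups against a brute-force per-column tally; SAM ingestion against the
same tally; p-distance against a naive per-column count; NJ against an
exhaustive topology search (all unrooted topologies, non-negative
least-squares branch fitting) on additive matrices up to 7 taxa; local
alignment against a quadratic-time Smith–Waterman dynamic program on pairs
≤ 60 bp; and the whole pipeline against the generator's truth table. The
package's own validation runs use: the full 155-sample cohort at default
coverage for retention/representative counts; a 60-sample cohort at 20×/12×
with zero errors for exact truth recovery; ten 25-sample mt-only replicates
at 35× and error 0.001 for the false-SNP rate (observed 0, bound < 1% of
sites); and ten 40-sample mt cohorts for bootstrap recovery of the planted
divergent group (support ≥ 70% expected in ≥ 9 of 10 seeds). The tree-stage
validation feeds haplotypes directly as representatives: read noise is
validated separately by the truth-recovery runs, and composing the two
would only add Monte-Carlo variance.

## Known limitations

The mapper is exact-seeded and ungapped: reads spanning indels or highly
diverged regions (> ~4 mismatches per 100 bp) go unmapped, which in heavily
diverged populations depresses coverage before it depresses accuracy. The
consensus is haploid-style by design and cannot report heteroplasmy or
mixed symbiont infections. Editing correspondence is positional only — no
statistical enrichment test is attempted, matching the descriptive scope of
the counts. NJ/p-distance trees are adequate for planted-structure recovery
but are not substitutes for model-based phylogenetics on real data, and
bootstrap supports on very short concatenations (≪ 1,000 sites) are
unstable. ITS2 typing trusts the reference labels and raw scores; it does
not model intragenomic ITS2 variation.
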