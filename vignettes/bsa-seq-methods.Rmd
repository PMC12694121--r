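---
title: "Methods: BSA-seq association scans, candidate regions, and KASP validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-seq association scans, candidate regions, and KASP validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bsamapr` maps a major trait locus from pooled sequencing of phenotypic
extremes in an F2 cross. This vignette explains the statistical model behind
each stage, the tunable parameters and their defaults, what the bundled
simulator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The experimental design being modelled

Two inbred parents — a wild-type line and an EMS-derived mutant with a
dominant long-spike allele — are crossed; the selfed F1 gives an F2 in which
the locus segregates 1:2:1. The longest- and shortest-spike tails (30 plants
each) are pooled equimolarly and sequenced to ~50× together with both
parents. After upstream variant calling, the analysis receives a four-sample
VCF with per-allele read depths (`AD`), a gene annotation (GFF3), a
reference sequence (FASTA) and per-plant phenotypes.

Sites are first filtered: every sample must reach a minimum coverage
(default 5×, applied per sample; whether such floors should apply per pool
or to the pool sum is ambiguous in common practice, so it is configurable),
each parent must be effectively homozygous (major-allele depth fraction
≥ 0.9 — "heterozygous parent" is otherwise undefined for an inbred), and the
parents must be fixed for different alleles, otherwise the site carries no
linkage information.

## SNP-index and Δ(SNP-index)

For pool *p* with read depth `M` on the designated parent's allele and `P`
on the other parent's allele, the SNP-index is `M / (M + P)`; reads matching
neither parental allele are excluded. The association statistic is the pool
difference `Δ = index_aa − index_ab` (long-spike minus short-spike pool).
The orientation parent defaults to the wild-type female parent of the
modelled cross and can be flipped; region calling uses |Δ| of windowed
means and is therefore orientation-invariant.

Sites whose index is below 0.30 in **both** pools are removed before
association. The alternative ("any pool below the floor") is offered as a
mode; the both-pool rule was chosen because a site that is extreme in one
pool only is exactly the signal being sought, while a site low in both is
uninformative.

Δ is averaged in fixed windows whose boundaries sit at multiples of the
step + 1 (default window = step = 500 kb). The fixed grid, rather than a
per-site sliding smooth, reproduces the round region boundaries
(…500,001) that windowed SNP-index scans conventionally publish; when a run
of consecutive above-threshold windows is reported as one region, the end
coordinate is the last window's end + 1 — the shared-boundary convention
under which a run of *k* windows has length `k·step + 1`.

**Threshold.** The conventional absolute cutoff for windowed |Δ| is 0.95.
That value is only attainable when extreme pools approach fixation for
opposite alleles — i.e. for additively scored or recessive-selected traits.
For a *dominant* trait, the short tail is fixed wild-type but the long tail
is a ~1:2 mixture of homozygous and heterozygous carriers, so |Δ| at a
fully linked locus tops out at 2/3 in expectation. Both readings are
therefore provided: `delta_mode = "absolute"` (the default, cutoff 0.95)
and `delta_mode = "quantile"`, which calls windows above the genome-wide
0.95 quantile of |windowed Δ| and is the practical choice for dominant
traits; the end-to-end recovery analyses in the test-suite use the quantile
mode for exactly this reason, while the no-locus null control uses the
absolute mode, where the expected spurious-region count is essentially
zero.

## Euclidean distance

At each site the two pools give base-frequency quadruples over (A, C, G, T);
`ED = sqrt(Σ_b (f_mut(b) − f_wt(b))²)` ranges from 0 to √2 and needs no
parental orientation. Because the raw statistic is noisy at ~50× depth, it
is smoothed along each chromosome and the *fitted* values are thresholded at
`median + k·SD` (default k = 3). Three numerical choices here were open:

* **Smoother.** A tricube-weighted local *linear* regression (`loess`,
  degree 1, exact "direct" surface) of `ED^power` on position, span 0.1.
  The power defaults to 1 so that thresholds stay on the raw-ED scale;
  powers of 4–5, as used by some pipelines to sharpen peaks, are
  configurable. The implementation was verified to machine precision
  against an independent per-point tricube weighted-least-squares solve.
* **SD convention.** The population (n-denominator) standard deviation of
  the fitted values, documented and tested; with thousands of sites the
  n vs n−1 distinction is immaterial, but the tests pin one convention.
* **Candidate SNPs.** Inside called regions, candidate SNPs must have
  main-allele frequency > 0.75 in the mutant (long-spike) pool and raw
  ED > 0.50 (strict inequalities). Note that under complete dominance the
  expected mutant-pool main-allele frequency at the causal site is 2/3, so
  this published criterion selects sampling-inflated linked sites rather
  than the causal site itself; the mapping conclusion rests on regions, not
  on individual candidate SNPs.

A caveat the tests make explicit: `median + 3·SD` is a *genome-wide
outlier* threshold. It presumes the trait-linked fraction of the genome is
small. If a large fraction of sites is elevated (as can happen in a
miniature genome), the SD term inflates and the threshold can exceed the
signal peak; see the simulator scaling note below.

## Regions, intersection, genes

Candidate regions are maximal runs of above-threshold entries; runs closer
than `max_gap_bp` (default 1 Mb) are merged and regions supported by fewer
than 3 markers are dropped. All coordinates are 1-based inclusive with
`length = end − start + 1` — the convention under which every row of the
published region tables shipped in `inst/extdata/` reproduces its printed
length exactly, which is how the convention was fixed. Two-method
intersection is plain interval intersection (via `GenomicRanges`),
commutative and idempotent; genes become candidates when they contain (or
are the annotated gene of) a candidate SNP inside an intersected region.

"Predominantly expressed" in the target tissue is operationalised as:
target-tissue expression ≥ 0.8 × the maximum over other tissues, and above
an expression floor (0.5 units). No published rule exists; both knobs are
exposed.

## Variant effect annotation

Location categories follow the standard 2-kb-flank / 2-bp-splice-window
definitions, with the combined classes (`exonic;splicing`,
`upstream;downstream`, `UTR5;UTR3`) produced when transcripts or
neighbouring genes disagree in exactly those ways. Coding effects translate
the reference and mutated codon under the standard nuclear code
(minus-strand transcripts reverse-complemented); indels are classified by
the length-mod-3 rule. All annotation failures — CDS length not divisible
by three, reference-base mismatch, untranslatable codons — map to an
`unknown` bucket rather than aborting the pipeline, mirroring how
production annotators bucket unresolvable transcripts. The annotator is
property-tested against an independent oracle that rebuilds the entire
mutant CDS and compares the translated proteins, over randomized toy genes
on both strands.

## KASP design, genotyping, association

Assay design enumerates allele-specific forward primers ending at the SNP
(lengths 19–30 nt; the two differ only at the 3′ terminal base) and common
reverse primers within an 80–150 bp product window, and keeps combinations
whose melting temperatures all fall in 59–65 °C and (by default) whose GC
content is 40–60 %; loci are retained only if the 301-bp SNP flank has
40–60 % GC and fewer than three exact genomic copies (both strands,
exact matching — the copy-counting method is not standardised, so exact
matching was chosen as the reproducible reading). Among feasible
combinations the ranking is deterministic: smallest Tm spread across the
three primers, then shortest product, then shortest primers. Failures
return a design-failure object naming the violated constraints rather than
an error. Fluorescent tail sequences are appended verbatim when supplied
and excluded from all checks.

Melting temperatures use the unified nearest-neighbor thermodynamic model
(duplex initiation, terminal A:T penalties, entropy salt correction
`0.368·(N−1)·ln[Na+]`, two-state formula with `C_T/4`), at 50 mM monovalent
salt and 200 nM total primer by default; fixture values in the tests were
frozen from an independent reference implementation and agree to well
under 0.5 °C.

Genotype calling clusters the normalised channel ratio `FAM/(FAM+HEX)` by
3-means with deterministic quantile initialisation (5 %, 50 %, 95 %), after
removing no-template controls (total signal below 0.2 × the median).
Clusters map to genotypes by ratio ordering. If adjacent cluster centres
are closer than 0.1 the samples are returned `undetermined` with a warning
rather than guessed. The genotype–phenotype test is Student's (pooled
variance) t between the two homozygote classes, with heterozygotes
summarised but excluded — the two-group comparison a dominant-trait marker
validation reports.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the modelled cross at desk scale: 200 F2
plants (the real population was 1120; configurable), 30-plant tail pools,
Poisson(50) pooled depth, three 2-Mb chromosomes with 500 markers each, a
single dominant locus (`additive_effect` 2.1 cm on a 7.0 cm wild-type base,
heterozygote equal to homozygote), Gaussian residual 0.8 cm absorbing the
polygenic background, a 90 % G:C→A:T mutant-parent allele spectrum, and a
0.001 per-read miscall rate. Two scaling choices deserve emphasis:

* **Recombination density, 200 cM/Mb.** The toy genome conserves the
  *total genetic length* of a plant genome (~1200 cM over 6 Mb) rather
  than its per-Mb recombination density. With a realistic per-Mb density a
  6-Mb genome would be ~6 cM — one effective locus, unmappable — and even
  at intermediate densities a third of the genome stays linked to the
  causal locus, which structurally breaks genome-wide outlier thresholds
  (see the ED caveat above). Conserving map length keeps the linked
  fraction at a few percent, the regime the published thresholds assume.
* **Causal position, 1.25 Mb.** Interior to a 500-kb scan window rather
  than on the 1.0 Mb window boundary, where "the region containing the
  locus" is ill-defined by a coin flip between two adjacent windows.

The sequencing-error model never converts one segregating allele into the
other (miscalls land uniformly on the two non-allele bases), so allele
counts are thinned but unbiased. The simulator does not model read-level
artifacts (FASTQ, alignment, mapping bias), indel mutational realism
(indels exist only as a site class), population structure, or polygenic
loci as explicit QTLs. Consequently, passing recovery tests show the
*statistical machinery* is correct under the stated model — they do not
show robustness to alignment artifacts or segregation distortion in real
data.

## Problem sizes used by the checks

The test-suite and the acceptance script use: 50 seeded replicates of the
default desk-scale dataset for causal-locus recovery (the causal locus must
fall inside the top-ranked region of both methods and of their intersection
in ≥ 95 % of replicates), 20 no-locus replicates for the null control
(mean spurious Δ-regions per genome ≤ 1 at the absolute 0.95 threshold),
1,000 random toy-gene variants for annotator/oracle concordance, and 20
seeded end-to-end KASP experiments on 91-plant panels (homozygote-class
p < 0.001 in ≥ 95 %). These sizes were chosen so the whole acceptance run
completes in about a minute on a single CPU while keeping the binomial
uncertainty of each rate well inside its acceptance margin.

## Known limitations

* The absolute Δ threshold 0.95 and the candidate-SNP MAF > 0.75 criterion
  are both unattainable *in expectation* under complete dominance; they are
  retained as published defaults, with the quantile mode and region-level
  mapping carrying the inference for dominant traits.
* The ED fitted-value threshold depends on the fraction of the genome
  linked to the trait; on very small genomes it must be interpreted with
  the scaling caveat above.
* Primer design screens thermodynamics and copy number only; it does not
  model secondary structure, primer-dimer formation, or tail interactions.
* Multiallelic VCF records are skipped (with a logged count), matching the
  strictly biallelic parent-vs-parent design.
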