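---
title: "Screening matched tumor/metastasis pairs for metastasis drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening matched tumor/metastasis pairs for metastasis drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

## The screening model

A metastasis is founded by a small number of seeding cells. A somatic SNV
that contributed to seeding must therefore satisfy two criteria that
`metscreen` applies literally:

1. **Metastasis enrichment.** The variant is effectively absent from the
   matched primary tumor. PT "absence" is assessed at read level, not
   caller level: we tolerate at most `pt_max_alt_reads` (default 1) alt
   reads at the site across all of the animal's PT call sets, pooling the
   PT samples of an animal because several primary tumors per animal are
   commonly combined at sequencing. The threshold is a package default;
   read-level evidence is stricter than requiring mere caller absence and
   is robust to a single stray error read.
2. **Presence in the seeding cell.** For a heterozygous variant at a
   diploid locus observed at allele fraction $v$, the fraction of cells
   carrying it is $\min(1, 2v)$. Requiring $v \in [0.30, 0.50]$ keeps
   variants carried by at least 60 % of the lesion while allowing for
   infiltrating normal cells. Both bounds are closed: 0.30 itself encodes
   the 60 % statement, so it must pass. The filter is applied to the raw
   observed VAF, not a purity-corrected one; purity correction would
   require a per-sample purity estimate the data do not provide.

Consensus across the three callers is taken at **site** granularity by
default — a call survives only if all three callers report the identical
(chrom, pos, ref, alt) in that sample — because site-level intersection is
the stricter reading and matches how overlapping call sets are usually
counted. A `gene` mode (a site survives if its gene is hit by every
caller, with non-tri-supported sites flagged) is retained for
completeness. Pooled counts for a consensus record come from the caller
with the highest depth at the site, ties broken by fixed caller-label
order; the choice only affects reporting, never membership.

Recurrence is classified per gene across **animals**, never lesions: two
metastases of one animal share ancestry and are not independent evidence.
A gene is `same_codon_recurrent` when two or more distinct animals share a
mutated codon (the alternate amino acids may differ),
`diff_codon_recurrent` when two or more animals carry mutations at
different codons, and `singleton` otherwise. Codon indices are always
reported against one canonical transcript per gene, fixed in the
annotation; multi-isoform renumbering is out of scope, and the transcript
id is recorded with every event. Sites with no gene assignment are
reported in a `non-coding/unassigned` bucket rather than dropped.

## Allele-specific copy number in F1 hybrids

Every strain-informative SNP in an F1 hybrid is heterozygous (one FVB
allele A, one partner allele B), so allele-specific copy changes move the
B-allele frequency away from 0.5. Under a mixture of tumor cells (fraction
$p$, the purity) and normal cells:

$$\mathrm{BAF}_{\text{loss of B}} = \frac{1-p}{2-p}, \qquad
  \mathrm{BAF}_{\text{gain of B}} = \frac{1+p}{2+p},$$

with the FVB-affected cases mirrored around 0.5. `expected_baf()` exposes
this closed form; the simulator draws counts from it and the tests check
convergence of segment-level BAF to it.

Segmentation is deliberately simple: counts are summed in 4000-bp tiles
(the same tile size used for the clonality fingerprints), tiles with fewer
than `min_snps = 3` SNPs are ignored, and runs of at least
`min_consecutive_bins = 5` informative bins deviating from 0.5 by more
than `baf_delta = 0.1` in the same direction form a segment. Up to
`max_bin_gap = 4` interrupting bins (sparse or individually neutral) are
tolerated inside a run: at realistic SNP densities a handful of tiles in
any true segment will fall below the SNP minimum by chance, and breaking
segments there would split real events. The conclusions this screen feeds
on are segment *presence and direction*, not breakpoint precision, so a
threshold-and-run-merge rule with exposed parameters is preferred over a
model-based segmenter; planted segments are recovered within one bin under
the default conditions. Loss versus gain is decided by the depth ratio
against the sample's median informative bin (dead band
`depth_ratio_eps = 0.05`); when the ratio is inconclusive the segment is
reported under the loss interpretation with `confidence = "low"`, and the
affected allele is always the under-/over-represented one — never a guess.
Samples on a homozygous FVB background are refused outright: without
heterozygous markers the allele-specific call has no support.

Metastasis-specific segments are those with no matched-PT segment of the
same state and allele at ≥ 0.5 reciprocal overlap (the subtraction rule is
a package default; 0.5 is the conventional reciprocal-overlap cutoff).
Recurrent regions are computed per state by collapsing each animal's
segments to their genomic union and decomposing the genome into maximal
intervals of constant animal support with support ≥ 2; each region carries
its length, animal frequency and supporter list. Animals increment the
frequency once regardless of lesion count.

## Fusion and SV curation

RNA (deFuse-like) and WGS (BreakDancer-like) candidates are normalized to
one schema but never merged into joint evidence — concordance between the
two sources is reported, not required. The filter battery:

- **Read-through exclusion** (RNA only): partners adjacent on the same
  chromosome and strand with no intervening gene and breakpoints running
  5′→3′ from the upstream into the downstream gene.
- **Support and distance**: ≥ 3 supporting reads; intrachromosomal
  partners ≥ 10 kb apart (closed threshold — exactly 10 kb passes);
  each breakpoint within 10 kb of a gene. Both 10-kb rules are applied to
  RNA and WGS candidates alike (configurable), as the dialects do not
  differ in their artifact modes here.
- **Repeat classification**: `both_repeat` / `one_repeat` / `single_copy`
  by point-in-interval lookup against a repeat BED. Manual curation of
  repeat artifacts is mechanized this way to be deterministic and
  testable. `both_repeat` is a hard exclusion; `one_repeat` is a flag.
- **Gene-family filter**: partners sharing a family id in an explicit map
  are excluded as presumptive alignment artifacts; a shared-prefix
  heuristic (trailing digits stripped) exists as a documented, off-by-
  default fallback. Unmapped genes yield `unassigned` and are kept.
- **Recurrence and read fraction**: candidates are `multi_animal`,
  `multi_partner` or `single`; RNA candidates with gene read totals get a
  read fraction, flagged when < 1 %.

Every input candidate appears in the audit exactly once with its full
filter vector; `final_keep` is the conjunction of the hard filters.

## Clonality fingerprints

Fingerprints code 4000-bp bins as −1/0/+1 (a bin takes the state covering
the majority of its bases; ties and neutral majorities give 0) and SNVs as
0/1, keeping features that are non-reference in at least 2 samples. The
distance is a weighted sum of Jaccard distance on the SNV block and
Manhattan distance on the CNV block scaled to $[0,1]$ (equal weights by
default); linkage is complete, chosen for conservative clade compactness.
Neither metric nor linkage is claimed to reproduce any particular
published figure — they are declared package defaults, configurable. A
principal-component view is omitted: clustering is the decision-bearing
output. Dendrograms are deterministic; ties are broken by sample-sheet
order.

An animal with ≥ 2 metastases is `monoclonal_seeding` when the smallest
dendrogram node containing all of its LM samples contains nothing else —
i.e. the metastases are each other's closest relatives. We interpret the
clade rule strictly (the matched PT inside the clade also breaks
monoclonality): if a metastasis is closer to the primary tumor than to its
sibling metastases, the two metastases do not share a private subclone and
were most plausibly seeded independently. Animals with < 2 clustered LMs,
or a clustering with no informative features, are `indeterminate`.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates call-level data (no reads): per-caller VCFs,
allele-count tracks, fusion/SV candidate lists, annotation, and a truth
file. The defaults are the study conditions the analysis assumes: mean
depth 40 reads (per-site depth Poisson-distributed, the standard
shot-noise model for a stated average), purity uniform on [0.60, 0.95]
(tumor purity is rarely reported; this range spans typical solid-tumor
estimates and is exposed in the config), four partner strains, six animals
with one PT and four LMs each (multiple metastases per animal are needed
for clonality calls to be meaningful), and driver lesion VAF equal to
purity/2 — a heterozygous variant truncal in the lesion — which lands in
[0.30, 0.475] by construction. Caller errors are independent across the
three pseudo-callers: false positives at distinct random sites (so
consensus removes them, which is the rationale for intersecting callers)
and per-caller dropout of true calls. Every third animal seeds
polyclonally, with two subclones each carrying half of the metastases and
the drivers riding on the first subclone, so discordant metastases exist
by construction.

With `deterministic_counts = TRUE` depths are fixed and alt counts
rounded, making noise-free planted-truth recovery an exact equality — the
end-to-end tests use this mode, because under binomial count noise a
driver planted at VAF 0.30 can legitimately be observed below the closed
bound.

The simulator does **not** model: read-level artifacts (mapping error,
strand bias), indels or multi-nucleotide variants, subclonal drivers
within a lesion, contamination of the PT by the metastatic clone, GC or
mappability waves in depth, or genuine inter-caller error correlation.
Passing tests on this cohort therefore certify the *screening logic*, not
caller behavior on real reads.

## Numerical choices and degenerate inputs

- Variant sites are 1-based (VCF convention); all interval arithmetic is
  0-based half-open (BED convention); converting between the two is an
  exact round trip.
- All thresholds are closed intervals where a boundary value encodes the
  stated rule (VAF 0.30, Phred 30, 10 kb, 3 reads).
- Empty cohorts, empty call sets and all-identical fingerprint samples are
  valid inputs producing empty (or zero-height) outputs, not errors;
  homozygous-background CNV requests and sub-3-caller consensus requests
  are errors by design.
- All randomness flows from the single simulator seed; the analysis stages
  are seed-free and byte-deterministic, and every output file carries the
  config hash.
- Test and example problem sizes (six animals, a 20-Mb four-chromosome toy
  genome, 1.5 informative SNPs per kb) were chosen as the smallest cohort
  on which every cohort-level feature of the method — recurrence across
  animals, recurrent regions, polyclonal seeding — is exercised
  non-trivially.

## Known limitations

- The CNV caller reports no integer total copy number and no genome-wide
  normalization; it answers "which allele, which direction, where", not
  "how many copies".
- Gene-level enrichment statistics for recurrent regions (GREAT-style) are
  out of scope; `assign_region_genes()` does flank-overlap assignment
  only.
- The canonical-transcript convention means codon indices can differ from
  other annotation pipelines for genes with multiple isoforms.
- Survival stratification against human cohorts and any read-level
  reanalysis are outside the package's scope.
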