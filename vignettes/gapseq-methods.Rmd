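---
title: "Gap-targeted scaffolding and window scans: methods and design notes"
author: "gapseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-targeted scaffolding and window scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapseqr)
```

## The problem

Long-read assemblies of repeat-rich plant genomes typically stall as a few
hundred contigs: coverage drops or repeats collapse exactly where contigs
end. Gap-targeted sequencing ("GAP-Seq") attacks this directly. Nanopore
adaptive sampling is pointed at the contig *ends*, so the sequencer spends
its throughput on molecules that can bridge two contigs; the resulting long
reads are then used to order and orient contigs into scaffolds. A second
cultivar assembled the same way provides independent bridging evidence:
where one of its scaffolds spans two scaffolds of the first assembly, the
pair can be joined into super-scaffolds, and the super-scaffolds are finally
anchored to the chromosomes of a related reference species to produce
pseudomolecules. `gapseqr` implements this computational pipeline, the
accompanying assembly QC, and the population-genomic window scan used to
compare two cultivars, with a seeded synthetic-data module so that every
stage is testable against known truth.

## Target design

`design_targets()` implements both published modes. In *plain* mode the
outermost `target_len` (default 5,000 bp) of every contig end is a target;
contigs no longer than twice the target length collapse to a single
whole-contig target. In *repeat-aware* mode an end is emitted only when the
merged repeat coverage of its terminal `repeat_window` (default 100 kb) is
**strictly** below `max_repeat_fraction` (default 0.50): repeat arrays at
contig ends defeat the enrichment because the sampled reads match everywhere.
Two choices deserve note:

* "the first 5,000 bp ... at the end of the contigs" is read as the
  *outermost* 5,000 bp of each qualifying end, keeping both modes
  geometrically identical. The alternative (an inner window) has no support
  in the rest of the procedure.
* Ends failing the repeat criterion are suppressed entirely rather than
  slid inward to a cleaner window. This is the simplest defensible rule;
  sliding is left as an extension.

Repeat intervals are unioned (via `IRanges`) before the fraction is
computed, so overlapping annotations never double-count.

## Read filtering and classification

`filter_reads()` keeps reads with length at least 20 kb and mean quality at
least Q10. Mean read quality is defined on the error-probability scale,
`-10 log10(mean(10^(-q_i/10)))` — the convention of common long-read
filters — because an arithmetic mean of Phred values would be dominated by
high-quality bases and admit reads with bad segments.

`classify_reads()` reproduces the post-hoc accounting of targeted reads.
A read's best alignment (most residue matches) decides everything: if it
overlaps no target the read is *off-target*; if it overlaps a target and
reaches within `eps` (default 100 bp — aligners rarely reach the exact
terminus) of the contig terminus with unaligned read bases continuing
outward, it is *gap-spanning* with that overhang; otherwise it stretched
toward the contig interior and is *proximal* — the published failure mode
that discarded more than half of the high-quality reads.

## The k-mer-pair link scaffolder

The scaffolder re-implements the LINKS idea. From each long read, k-mer
pairs are taken at offsets 0, `step`, 2·`step`, ... with a fixed separation
`d` between the two k-mers. Each k-mer is looked up in an index of k-mers
that occur **exactly once** (in canonical form, i.e. the lexicographic
minimum of a k-mer and its reverse complement) across the entire contig
set; multi-copy k-mers are blacklisted and can never contribute evidence —
repeats are precisely the stated failure mode, so ambiguous matches are
worth nothing. A pair whose two k-mers land on different contigs implies an
adjacency of two contig ends, a relative orientation, and a gap size

```
gap = d - dist_a - dist_b
```

where each `dist` is the distance from the k-mer to the end of its contig
in the direction the read travels. Pairs accumulate into edges between
contig ends; within an edge, pairs whose implied gap deviates from the edge
median by more than `distance_error * d` are discarded. The median is taken
over the edge's full set of estimates (not a running median) so that the
result is invariant under permutation of read and contig order — one of the
module's tested properties.

Joining is deliberately conservative, with the published tuned values as
defaults: an end's best edge is usable only if its support reaches
`min_links` (15) and the second-best support divided by the best is at most
`max_link_ratio` (0.1); a join requires usability from **both** ends.
Remaining degrees of freedom are fixed deterministically: ties in edge
ranking break on the lexicographic key of the partner end; cycle components
(possible in principle, rare in practice) are broken at their
lowest-support edge; scaffolds are named in descending total-length order.
Estimated gaps are `max(round(median), 1)` — negative implied gaps
(overlapping contigs) floor to a 1-N gap because sequence-level overlap
resolution is out of scope. The default extraction `step` of 2 keeps
pairing dense at negligible cost; the original tool's stride is not
documented, and the statistic is insensitive to it once support saturates.

## Cross-assembly bridging and pseudomolecules

The published procedure joined scaffolds "manually" when one cultivar's
scaffold bridged two scaffolds of the other. `apply_bridges()` encodes that
rule with explicit geometry and conflict handling, since no manual
tie-breaking can be reproduced:

* A bridge requires exactly two anchor chains of at least `min_anchor`
  aligned bases (default 20 kb), on disjoint and ordered query intervals,
  each within `end_window` (default 500 kb) of the respective scaffold end,
  and with strand/side geometry consistent with walking along the bridge.
* Two bridges claiming the same scaffold end with different partners are
  **all** dropped — conservative, because the evidence is contradictory.
* Each join inserts exactly `join_gap` Ns (default 100, the published
  join). Bridging cycles drop their weakest bridge.

`anchor_to_reference()` replaces gene-level synteny anchoring with
alignment-share anchoring: a super-scaffold is assigned to the chromosome
holding the largest share of its aligned bases provided that share reaches
`min_cov_frac` (default 0.3); orientation is the majority strand; within a
chromosome, super-scaffolds are ordered by the weighted median reference
position of their aligned bases and concatenated with `join_gap` Ns.
Sequences failing the share threshold are reported as unplaced, mirroring
the retained unplaced scaffolds of the published assemblies. The 100-N gap
between super-scaffolds inside a pseudomolecule is reused by analogy with
the bridging gap; the original gap length at this step is not stated.

## Assembly QC

`nx_stats()` computes N50/L50 by the cumulative-sum definition.
`coverage_fold()` is a plain ratio, rounded only at the reporting layer.

`estimate_genome_size()` consumes a k-mer multiplicity histogram. The
counts are densified, smoothed with a centred moving average (window 3 —
the minimal smoothing that suppresses single-bin noise), the error cutoff
is the first local minimum scanning up from multiplicity 1 (error k-mers
dominate low multiplicities), and peaks are local maxima above the cutoff.
A peak must also reach `min_peak_frac` (default 0.05) of the tallest
smoothed count above the cutoff: the sparse high-multiplicity tail of a
real spectrum contains single-count plateaus that would otherwise register
as maxima. Two peaks flag a heterozygous spectrum; the estimate divides the
k-mer mass above the cutoff by the **highest-multiplicity** peak, treating
it as the homozygous peak — consistent with a single reported peak
multiplicity per cultivar despite visibly two-peaked spectra.

`telomere_scan()` counts non-overlapping copies of the telomere motif and
of its reverse complement in the terminal window of each sequence end and
reports the better orientation per side. The motif is configurable with the
canonical plant repeat TTTAGGG as default (window 3,000 bp, at least 10
copies); the published QC confirmed telomere repeats at all pseudomolecule
ends but does not print the motif.

## Windowed population statistics

`filter_snps()` applies the published VCF filters in a fixed order:
genotypes below `min_dp` (5) become missing; sites survive if they are
biallelic SNPs with QUAL at least `min_q` (200), post-mask call rate at
least `max_missing` (0.8), and alternate-allele frequency within
`[maf, max_maf]` = [0.05, 0.95] on the non-missing genotypes. `max_maf` is
honoured literally as an upper bound on the alternate-allele frequency,
matching the quoted parameter string. Output is coordinate-sorted, so it is
identical for any input record order.

`tajima_d()` implements the 1989 statistic: `D = (pi - S/a1) /
sqrt(e1*S + e2*S(S-1))` with the standard constants. Nucleotide diversity
and segregating sites accumulate per site with each site's observed allele
count, which handles missing genotypes naturally. The constants are
computed from the mean observed sequence count over segregating sites,
using generalised harmonic numbers (`digamma`/`trigamma`), which reproduce
the exact integer-n sums and extend smoothly to fractional means; a
`per_site_watterson` flag accumulates Watterson's estimator per site
instead. With complete data both conventions coincide exactly, and the
implementation is tested against a brute-force pair-enumeration oracle to
1e-9.

`wc_fst()` implements the Weir–Cockerham (1984) theta-hat for two
populations from per-site variance components (among populations, among
individuals within populations, within individuals), combined across a
window as a ratio of sums. Sites where either population has fewer than two
called genotypes are skipped; the estimate is missing when the denominator
is zero. Small negative estimates are legitimate for this estimator and are
not truncated.

`window_scan()` tiles each sequence with non-overlapping windows (default
100 kb) including the trailing partial window; half-open boundaries put a
SNP at position `w` into the second window.

## Permutation nulls

The published scan reports windows significant at p < 0.01 from 10,000
permutations without stating what was permuted. Two schemes are
implemented, chosen to match each statistic's logic:

* **F_ST (high tail):** sample-to-population labels are permuted and every
  window's F_ST recomputed. Label permutation is the standard null for
  differentiation: it preserves each window's site configuration while
  destroying population structure.
* **Tajima's D (low tail):** D is a single-population statistic, so label
  permutation is undefined. The null instead resamples sites without
  replacement into pseudo-windows of matched SNP count, asking whether a
  window's D is low relative to same-sized draws from the genome-wide site
  pool.

Both use the add-one estimator `p = (1 + #extreme) / (n_perm + 1)`, so p is
never exactly 0. Flagging uses `p < alpha`; `alpha = 1` is treated as the
explicit degenerate threshold (every window with a defined statistic),
since add-one p-values can equal 1 exactly. High-F_ST windows intersected
with per-population low-D windows give the regions of between-cultivar
differentiation plus within-cultivar uniformity. No multiple-testing
correction is applied to window flags, matching the published raw
permutation p-values. When the sample configuration admits fewer than two
distinct label partitions the F_ST p-values are reported as 1 with a
warning.

## What the simulator does and does not emulate

The `simulate_*` generators are pure functions of their parameters and
seed. `simulate_genome()` plants telomere arrays (at least 30 motif copies;
the tail end carries the reverse-complement array) and a fixed 500-bp
repeat cassette at a chosen density, with every placement recorded.
`fragment_genome()` cuts each chromosome into contigs with withheld gaps
and records the true adjacency list, gap sizes, and any
reverse-complemented contigs, so concatenation reproduces the genome
exactly. `simulate_long_reads()` samples reads genome-wide or deliberately
across true gaps (`span_gaps`), applies substitution errors only, and gives
each read a constant quality string at the Phred equivalent of the error
rate — this makes mean-quality filtering exact and keeps the k-mer linking
tests interpretable. `simulate_kmer_histogram()` is a spectral model
(Poisson multiplicities per genomic k-mer plus unique error k-mers), not a
k-mer counter. `simulate_two_pop_genotypes()` draws population allele
frequencies from the Balding–Nichols Beta distribution parameterised
directly by the target F_ST — the minimal standard model for a fixed
differentiation level — and plants outlier windows as fixed differences.

None of this emulates real ONT error profiles (no indels, no homopolymer
effects), linkage disequilibrium, recombination, or realistic site
ascertainment. Passing tests therefore demonstrate algorithmic correctness
on data satisfying the models' assumptions, not end-to-end performance on
real sequencing data; with indel-rich reads the exact-match k-mer pairing
would need shorter k or higher support thresholds.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for reproducible desk-scale
runs: scaffolding uses a 1-Mb genome in 10 contigs with 200 gap-spanning
reads at 2% substitution error, at proportionally scaled parameters (k =
21, d = 2,000, 5 links minimum, ratio 0.1) — the published genome-scale
values (k = 51, d = 20,000, 15 links) are the package defaults. The
permutation-uniformity check uses 1,000 windows by 1,000 permutations;
oracle agreement uses 500 random windows at tolerance 1e-9; genome-size
recovery uses a 1-Mb, 40-fold, 0.2%-error spectrum with a 5% tolerance.
Coordinates are 0-based half-open everywhere inside the package; AGP output
converts to 1-based inclusive at the writer boundary, the only place a
conversion happens.

## Known limitations

* Bridging requires *exactly* two qualifying anchors per bridge sequence;
  a bridge overlapping three scaffolds contributes nothing (conservative).
* The scaffolder never merges overlapping contigs; negative gap estimates
  floor at a 1-N join.
* `wc_fst()` supports exactly two populations, as in the two-cultivar
  comparison it implements.
* Genome-size estimates inherit the biases of k-mer spectra: high
  heterozygosity and repeat content shift mass between peaks, and the
  published estimates themselves undershot the final assembly sizes.
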