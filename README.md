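# gapseqr

Finishing a long-read plant genome assembly usually stalls at the contig
ends: coverage thins out or repeats collapse exactly where contigs stop, and
a few hundred contigs refuse to become chromosomes. **gapseqr** implements
the computational side of gap-targeted sequencing (GAP-Seq), a
genome-finishing strategy in which nanopore adaptive sampling is aimed at
contig ends so the sequencer preferentially yields reads that bridge
assembly gaps. The package is written for assembly practitioners and
population geneticists who want the full pipeline — and its statistics —
reproducible and testable on synthetic data.

It provides:

* **Target design** — adaptive-sampling targets at contig ends: the
  outermost 5,000 bp of each end (plain mode) or only ends with < 50%
  repeat coverage in the terminal 100 kb (repeat-aware mode).
* **Read QC** — length (≥ 20 kb) and mean-quality (≥ Q10) filtering, with
  mean quality defined on the error-probability scale
  `-10·log10(mean(10^(-q_i/10)))`, and classification of targeted reads as
  gap-spanning, proximal, or off-target.
* **k-mer-pair link scaffolding** — a LINKS-style scaffolder: two k-mers a
  fixed distance *d* apart on one read, each occurring exactly once in the
  contig set (canonical form), vote for a contig-end adjacency with implied
  gap `d − dist_a − dist_b`; joins require `min_links` supporting pairs and
  a second-best/best support ratio ≤ `max_link_ratio` from both ends.
  Defaults are the conservative published set (k = 51, 15 links, d =
  20,000 bp, 2% distance error, ratio 0.1).
* **Cross-assembly bridging** — when a scaffold of one assembly anchors to
  the ends of exactly two scaffolds of the other, those two are joined with
  100 Ns into super-scaffolds; conflicting bridges are dropped wholesale.
* **Pseudomolecule construction** — super-scaffolds are assigned to
  reference chromosomes by aligned-base share, oriented by majority strand,
  and ordered by weighted median reference position.
* **Assembly QC** — N50/L50, coverage fold, k-mer-histogram genome-size
  estimation (error cutoff at the first spectrum minimum, heterozygous
  two-peak detection, size = k-mer mass / homozygous peak), and telomere
  end scanning (default motif TTTAGGG).
* **Population-genomic window scan** — VCF filtering (minDP 5, minQ 200,
  alt-frequency in [0.05, 0.95], call rate ≥ 0.8), non-overlapping 100-kb
  windows of Tajima's D per population and Weir–Cockerham θ̂ between two
  populations, and permutation outlier detection (label permutation for
  F_ST, SNP-count-matched site resampling for D; add-one p-values; flags at
  p < 0.01 from 10,000 permutations by default), including the
  high-F_ST ∩ low-D intersection per population.
* **Synthetic data** — seeded generators for genomes with telomeres and
  repeat cassettes, fragmentations with withheld gaps and known adjacency
  truth, error-bearing long reads (optionally placed across true gaps),
  toy k-mer spectra, truth-derived PAF alignments, and Balding–Nichols
  two-population genotypes with plantable outlier windows.

## Worked example

Simulate a 1-Mb genome, shatter it into 10 contigs with withheld gaps,
design repeat-aware targets, sequence gap-spanning reads at 2% error, and
scaffold at proportionally scaled parameters:

```r
library(gapseqr)

truth <- simulate_genome(n_chrom = 1, chrom_len = 1e6, repeat_density = 20, seed = 101)
frag  <- fragment_genome(truth, n_contigs = 10, min_gap = 200, max_gap = 1000,
                         seed = 102, prefix = "ctg")
nx_stats(frag$contigs)[c("n_sequences", "n50")]
#> contigs: 10   N50: 126593

repeats <- lift_to_contigs(frag, truth$repeats)
targets <- design_targets(frag$contigs, repeats, target_params(mode = "repeat_aware"))
#> 20 targets, 100,000 bp total (5,000 bp at both ends of all 10 contigs)

reads <- simulate_long_reads(truth, n_reads = 200, mean_len = 12000, len_sd = 1500,
                             error_rate = 0.02, seed = 103,
                             span_gaps = TRUE, frag = frag)
kept <- filter_reads(reads, read_filter_params(min_qv = 10, min_len = 5000))
#> 200 / 200 kept (simulated reads carry constant Q17 strings at 2% error)

res <- link_scaffold(frag$contigs, kept$kept,
                     link_params(k = 21, min_links = 5, pair_distance = 2000,
                                 distance_error = 0.02, max_link_ratio = 0.1))
nx_stats(res$sequences)[c("n_sequences", "n50")]
#> scaffolds: 1   N50: 1000000

telomere_scan(res$sequences)
#>          seq_id side   motif copy_count   density  hit
#> 1 scaffold_0001 head TTTAGGG         50 0.1166667 TRUE
#> 2 scaffold_0001 tail CCCTAAA         50 0.1166667 TRUE
```

All ten contigs reassemble into a single scaffold whose N50 equals the
genome length, and the telomere scan recovers both chromosome ends — the
tail end as the reverse-complement motif, as on a real forward strand.
`res$layouts` is AGP-ready (`write_agp()`), and `res$edges` /
`res$rejected` record every accepted and rejected link edge with support,
gap estimates, and rejection reasons.

For the two-population scan:

```r
sim <- simulate_two_pop_genotypes(n_sites = 2000, n_per_pop = 50,
                                  fst_target = 0.1, seed = 32)
ws  <- window_scan(sim$gm, scan_params(window = 1e5),
                   seq_lengths = c(chr_sim = 5e6))
mean(ws$fst, na.rm = TRUE)
#> 0.0981  (Balding–Nichols target 0.1)
po  <- permutation_outliers(ws, sim$gm,
                            scan_params(window = 1e5, n_perm = 1000, alpha = 0.01, seed = 9))
```

`po` adds `p_fst_high`, per-population `p_d_low_*`, and the flag columns,
including the `flag_intersect_*` windows that are both differentiated
between populations and unusually uniform within one.

A thin command-line wrapper over the same functions ships at
`inst/scripts/gapseq.R` (subcommands `stats`, `genomesize`, `telomere`,
`coverage`, `targets`, `filter-reads`, `classify`, `scaffold`, `bridge`,
`anchor`, `popgen`, `sim-*`).

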