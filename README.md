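# pasurveil

PA-seq analysis of adenylated RNA surveillance substrates in
knockdown-versus-control designs.

## What it is for

Nuclear RNA surveillance (TRAMP/NEXT complexes built around the Mtr4
helicase, feeding the exosome) tags byproduct and defective RNAs with short
poly(A) tails and degrades them.  Depleting Mtr4 stabilises these normally
invisible species, and polyadenylation-site sequencing (PA-seq) — where each
read pair reports the genomic coordinate of a transcript's last templated
nucleotide before its poly(A) tail — turns a knockdown/control comparison
into a genome-wide screen for surveillance substrates: rRNA 5'ETS fragments
adenylated at the A0 processing site, snoRNAs over-trimmed by 1–3 nt, and
the 5' leader fragments that Drosha cleavage releases from primary miRNA
transcripts, whose adenylated 3' ends coincide exactly with the Drosha
cleavage site.

`pasurveil` is aimed at analysts who want this pipeline as tested,
reusable R functions, plus a synthetic-data generator that emulates the
library chemistry with planted ground truth so every stage can be verified
without downloading sequencing data.

## The method in brief

* **Library model.** The 3'-end mate begins with a `TTT` tag immediately
  adjacent to the complement of the 3'-terminal residue; read 1 opens with
  a 5-nt sample barcode.  Demultiplexing is exact-match; tag orientation
  trims exactly three T's.
* **Mapping.** An exact k-mer pigeonhole mapper (≤ 2 substitutions per
  mate, inward-facing pairs, span ≤ 1000 bp).  2–9 candidate positions are
  assigned uniformly at random (seeded); ≥ 10 are discarded, as are
  placements overlapping repeat intervals.  Each accepted pair is a *hit*
  at one (contig, strand, position).
* **Sites.** Per-nucleotide tallies; sites with < 5 reads per run flagged;
  internal-priming removal when the 20 genomic bases downstream contain
  ≥ 6 consecutive A or ≥ 15 A of 20; reads-per-million normalization.
* **Peaks.** Gaussian-KDE clustering (bandwidth 5 bp); per cluster the
  mode, the type-1 empirical 95% interval of read positions, the *narrow*
  flag (width < 10 bp) and mode ± 2 window sums.
* **Differential layer.** Per-gene modal poly(A) sites within ±50 of
  annotated 3' ends (null-mRNA check: R² of log10 RPM, log2-ratio
  histogram with a (−0.2, 0.2] centre bin); peak categorization
  (refseq_pa → repeat → neither); ranking of "neither" peaks by KD/control
  window-sum ratio with `N.D.` for control-zero; a directed miRNA-leader
  scan at annotated Drosha sites; strand-aware 3'-end offset profiles
  pooled over identical tandem feature copies.

See the methods vignette (`vignettes/pa-seq-surveillance.Rmd`) for the
full model, parameter rationale and design decisions.

## Worked example

```r
library(pasurveil)
res <- run_paseq_pipeline(seed = 1)   # simulate + analyse, ~20 s

res$map_summary
#>   sample_id raw_reads mapped_reads percent_mapped genomic_positions
#> 1     ctrl1    198966       196881           99.0                50
#> 2       kd1    198975       196611           98.8                50

head(res$ranked[, .(contig, strand, mode_pos, kd_reads, ctrl_reads,
                    ratio_label)], 3)
#>    contig strand mode_pos kd_reads ctrl_reads ratio_label
#> 1:   chrS      +    43200     1669         29        57.6
#> 2:   chrS      -    41511     1052         19        55.4
#> 3:   chrS      +    32951      969        119        8.14

res$leaders[, .(mirna, drosha_site, modal_pos, kd_reads, ctrl_reads)]
#>       mirna drosha_site modal_pos kd_reads ctrl_reads
#> 1: mir301-1       41511     41511     1052         19
#> 2: mir302-1       43200     43200     1669         29

profile_window_fold(res$sno_profile, -3:-1, res$kd, res$ctrl)$fold
#> [1] 8.195426
res$a0_fold$fold
#> [1] 8.142857
c(res$r2$r2, res$histogram$frac_within_twofold)
#> [1] 0.9997159 1.0000000
```

Reading the output: the two top-ranked "neither" peaks are the planted
miRNA 5' leaders — their modal positions sit exactly on the annotated
Drosha cleavage sites and they accumulate ~55–58-fold in the knockdown
(planted fold 60, attenuated by sampling); the snoRNA −3..−1 over-trimmed
species recover ~8.2-fold (planted 9) and the 5'ETS A0 window ~8.1-fold
(planted 8); the null mRNA background shows R² ≈ 1 between conditions with
100% of genes within a two-fold difference, and both internal-priming
traps are removed by the templated-adenosine filter.

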