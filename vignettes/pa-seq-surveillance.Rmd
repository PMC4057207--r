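---
title: "PA-seq analysis of RNA surveillance substrates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PA-seq analysis of RNA surveillance substrates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasurveil)
library(data.table)
```

# The problem

Nuclear RNA surveillance marks defective or byproduct RNAs with short
poly(A) tails (via TRAMP/NEXT-type complexes built around the Mtr4
helicase) and hands them to the exosome for 3'→5' degradation.  When Mtr4
is depleted, these normally short-lived adenylated species accumulate.
Polyadenylation-site sequencing (PA-seq) captures adenylated 3' ends at
single-nucleotide resolution, so a knockdown-versus-control comparison
reads out surveillance substrates directly: rRNA 5'ETS fragments ending at
the A0 processing site, snoRNAs over-trimmed by one to three nucleotides,
and — in animal cells — the capped 5' leader fragments that Drosha cleavage
releases from primary miRNA transcripts, whose adenylated 3' termini fall
exactly on the Drosha cleavage site.

`pasurveil` implements the complete analysis as a tested pipeline, and a
synthetic-data generator that emulates the library chemistry with planted
ground truth, so every stage is verifiable without any sequencing download.

# Library model and read preparation

The protocol fragments RNA, reverse-transcribes with a biotinylated
oligo(dT)/deoxyU/TTTVN primer, and cleaves the primer at the uracil so that
the 3'-end read begins with exactly **three T's immediately adjacent to the
complement of the transcript's 3'-terminal templated residue**.  Read 1
opens with a 5-nt sample barcode.  The simulator reproduces exactly this
structure: for a transcript 3' end at genomic position $p$ (strand-aware),
the 3' mate is `TTT` + reverse complement of the template ending at $p$;
the 5' mate reads inward from the other end of a size-selected fragment on
the opposite strand.  Which physical mate carries the tag is randomized, so
the read-prep stage must detect it rather than assume it.

Read preparation therefore does two things, both deliberately strict:

* **Demultiplexing** requires a perfect 5-mer barcode match (no rescue);
  anything else is counted as unassigned.
* **Orientation** designates the mate that begins with `TTT` as the 3'
  read and trims exactly three T's.  The chemistry guarantees the tag is
  exactly three T's long, so a fourth leading T is treated as templated
  sequence (it is the complement of a 3'-terminal A-adjacent context); no
  longer T-run is scanned.  Pairs where both mates begin with `TTT`
  (ambiguous) or neither does (tag lost to error) are rejected with
  distinct reason codes, and 3' reads shorter than 8 nt after trimming are
  dropped as unmappable.

# Mapping and the adenylation-site call

Alignment is a purpose-built exact k-mer index (default $k = 10$) with
pigeonhole seeding: seeds are tiled every $k$ bases plus a flush seed at
the read end, so for reads of length $\ge 3k$ and at most 2 substitutions
the candidate set provably equals a brute-force scan of every genomic
offset on both strands (the test suite asserts this against an independent
`Biostrings::matchPattern()` enumeration).  Indels are not modelled: at toy
scale, exactness of the candidate set is worth more than edit-distance
generality, and substitution-only matching keeps the mapper's behaviour
fully checkable.

A candidate position for a pair is a placement of the 3' read with at most
2 mismatches that has a compatible 5'-mate placement: same contig, opposite
strand, inward-facing, outer span at most 1000 bases (the 250–400 bp
library makes real spans much tighter; 1000 is a safe ceiling).  The rules
for multiple candidates follow the field convention for this assay:

* 0 candidates → unmapped;
* 2–9 candidates → assigned to one **uniformly at random** with a seeded
  generator (this is what makes identical tandem snoRNA copies analysable:
  pooled per-copy-group profiles are unbiased);
* ≥ 10 candidates → discarded.  Random assignment is only defensible for a
  handful of placements; discarding is the conservative reading for the
  rest.
* a chosen placement overlapping a repeat interval → discarded.  The
  repeat check runs **after** random assignment; filtering candidate lists
  before assignment would bias the per-copy uniformity of the survivors.

Each accepted pair is one *hit*: adenylation at the genomic base adjacent
to the trimmed tag, reported on the transcript strand (a 3' read aligning
to the minus strand derives from a plus-strand transcript ending at its
rightmost aligned base, and vice versa).

# Site table, filters, normalization

Hits are tallied per (contig, strand, position, sample).  Three
independent annotations are then applied:

* **Minimum reads.** Sites with fewer than 5 reads in a sample are flagged
  per sample (runs are never pooled for this; each sequencing run is
  normalized and thresholded on its own).  Directed feature queries (the
  miRNA leader scan, mode-anchored window sums) bypass this flag: a
  directed question at a known coordinate legitimately reports 3 reads.
* **Templated adenosine (internal priming).** Oligo(dT) can prime on
  genomically encoded A-runs, producing apparent 3' ends with no
  adenylation event.  A site is flagged when the 20 genomic bases
  immediately *downstream* in transcript orientation contain ≥ 6
  consecutive A's or ≥ 15 A's in total.  The window is strictly downstream
  (positions +1..+20), not centred, because internal priming mimics a tail
  3' of the reported end; anchoring the rule at the site (rather than at a
  cluster) makes it testable at single-nucleotide resolution while
  removing exactly the clusters whose mode is affected.  Windows truncated
  at a contig end are evaluated on the available bases with both
  thresholds scaled proportionally (rounded up).  Flagged sites are
  excluded from all peak and differential computations.
* **RPM.** Reads per million mapped reads of the same run — the assay's
  only normalization.  No cross-sample quantile/TMM-style adjustment is
  applied, deliberately: the quantity of interest is per-run relative
  abundance, and the differential layer works on raw window counts and
  RPM ratios.

# Peak calling

Peaks are maximal contiguous regions where a Gaussian kernel density of
read counts stays above a threshold:

$$d(x) = \sum_s c_s \, e^{-\frac{(x - p_s)^2}{2 b^2}}$$

per contig and strand, evaluated within four bandwidths of any site.
Defaults: bandwidth $b = 5$ bp, because PA-seq 3' ends are
near-single-nucleotide (DNase-scale density defaults from generic
feature-density callers would be far too wide); threshold = the density a
lone 5-read site contributes at distance $2b$ from itself
(`default_density_threshold()`), so isolated sites at the minimum read
count always form a peak.  Both are configurable.

Per cluster the focal (knockdown) sample defines: the **mode** (maximum
raw count; ties break to the most 5' position in transcript orientation,
deterministically); the **95% interval** — inverse-ECDF (type-1) 2.5% and
97.5% quantiles of the read-position multiset, each read contributing its
position once; and the **narrow** flag, width < 10 bases.  Window sums are
raw reads over mode ± 2.  The "± 2" five-position window is the package's
reading of the assay's "+2 bp relative to the mode" summation convention —
a symmetric window is the only interpretation under which the published
window sums are self-consistent, so it is adopted as an explicit
convention throughout (peaks, leader scan, A0 query).

# Differential layer

* **Null mRNA check.** Per gene, the modal poly(A) position among retained
  sites within ±50 bases of the annotated 3' end (ties: closest to the
  annotated end, then most 5'; a one-sided window is available behind a
  flag).  The ±50 reading of "within +50 bases" mirrors the window-sum
  convention above.  Reproducibility is summarised as $R^2$, the squared
  Pearson correlation of $\log_{10}$ modal-site RPM over genes detected in
  both samples (log scale is the field convention for such dot plots;
  zero-signal genes are excluded and counted, and the correlation's sign
  is reported alongside so anti-correlation cannot masquerade as
  agreement).  Knockdown/control log2 ratios are binned with a centre bin
  (−0.2, +0.2] and 0.4-wide bins labelled by their outer edge, and the
  fraction within two-fold (|log2| < 1) is reported.
* **Categorization and ranking.** Every peak gets exactly one category by
  fixed precedence: `refseq_pa` (mode within ±50 of an annotated gene end,
  matching strand) → `repeat` (mode inside a repeat interval) → `neither`.
  "Neither" peaks are ranked by the knockdown/control ratio of mode ± 2
  raw window sums.  Control-zero peaks are reported as `N.D.` (not
  detected) and ranked first by default rather than given a pseudocount; a
  pseudocount exists only as a histogramming option.  No p-values or FDR
  are computed — the method ranks by raw ratio, and the package follows
  that design rather than bolting on a testing layer the sampling model
  would not support.
* **miRNA 5' leaders.** For every annotated hairpin, the predicted Drosha
  cleavage site is the base immediately 5' of the hairpin in transcript
  orientation, taken from the annotation (no de novo hairpin or cleavage
  prediction).  Reads are summed over the site ± 2 on the host strand,
  bypassing the minimum-read flag; hairpins with zero reads in both
  conditions are suppressed unless requested.
* **Feature profiles.** Offset profiles around a feature's annotated 3'
  end (offset 0 = last templated base; negative = inside the feature),
  pooled over identical tandem copies of a copy group, with cumulative
  folds over caller-specified sub-ranges (e.g. −3..−1 for over-trimmed
  snoRNA species).  A companion check reports the fraction of 5' mates
  mapping fully inside the feature — distinguishing genuine processing
  products of a short RNA from read-through transcription.

# Coordinates

All in-memory coordinates are 1-based, closed intervals — the
R/Bioconductor (IRanges) convention — with annotated 3' ends as the last
transcribed base on the feature's strand.  BED output is converted to
0-based half-open at the file boundary; GFF stays 1-based; reported mode
coordinates are 1-based.

# What the synthetic generator emulates — and what it does not

`build_toy_genome()` plants, under the default layout: 20 null
protein-coding genes (poly(A) sites, no fold change, alternating strands);
an rRNA unit with A', A0 and 18S-junction processing sites and an
A0-terminating species at fold 8; four identical tandem snoRNA copies
(one copy group) with species at offsets 0 (fold 1), −1..−3 (fold 9 — the
over-trimmed surveillance substrate) and +2; two miRNA clusters inside
host transcripts (one minus-strand, two hairpins; one plus-strand) whose
5'-most hairpin has a planted adenylated leader at fold 60; two repeat
intervals, one harbouring a planted site; two internal-priming traps
(an 8-A run, and a 17-of-20 A window with runs capped at 5, exercising
both filter branches separately); and two null non-coding sites.  Every
true site gets a non-A terminal base and an A-poor downstream 20-mer, so
the templated-A filter has an exact planted truth: traps must all be
flagged, true sites never.

Default study conditions: 2×10^5 read pairs per sample, 36-nt reads,
150–400 bp fragments (capped at the species length, which both respects
size selection of short RNAs and guarantees that exactly the configured
number of pairs is emitted), substitution errors at 0.1% per base
(typical short-read error rates), one control and one knockdown sample.
Abundances are multinomial weights; control weights were chosen so planted
surveillance species are rare against the mRNA background (the knockdown's
extra reads shift totals by < 4%, so raw ratios track planted folds
closely), and the planted folds (60 / 9 / 8) are the magnitudes the assay
is expected to resolve at this depth.

Not modelled, by design: positional micro-heterogeneity of cleavage
(every planted species ends at one exact base — real peaks are a few bases
wide), quality-score variation, PCR duplicates, adapter read-through,
rRNA-depletion or fragmentation biases, and poly(A)-tail length (the
chemistry removes the tail before sequencing; only the 3-T tag is
emitted).  Passing tests therefore demonstrate correctness of the
*analysis logic* under a faithful model of the library structure — not
robustness to every artefact of real libraries.

# Statistical checks on recovery

Planted folds are verified against Monte-Carlo intervals that reproduce
the simulator's actual sampling design (binomial counts at the site's
weight within each condition's multinomial total).  Because four folds
(two leaders, snoRNA trim, A0) are asserted jointly in one fixed-seed run,
the per-fold quantiles are Bonferroni-corrected (0.05/4, two-sided) so the
family of checks forms a simultaneous 95% interval; per-fold 95% intervals
would false-alarm on roughly one seed in five while saying nothing more.

# Problem sizes

The shipped tests and the acceptance script use: a 60-kb default toy
genome at 2×10^5 pairs per sample for end-to-end recovery; a 50-kb genome
at 10^4 pairs (1% error) for the mapper-versus-brute-force oracle and the
multimap uniformity chi-square (≥ 4000 reads over 4 identical copies,
α = 0.01); a 30-kb genome at 10^3–10^4 pairs for module-level checks.
These sizes were chosen so each property is measured with comfortable
statistical margin while a full suite run stays interactive.

# Known limitations

* The mapper is substitution-only and exact by construction; it is a
  verifiable stand-in for production aligners at toy-genome scale, not a
  general-purpose aligner.
* Site-anchored templated-A filtering can differ from cluster-anchored
  filtering for broad clusters whose mode sits just outside an A-rich
  context; the site-anchored rule was chosen because it matches the
  priming mechanism and is exactly testable.
* With identical tandem copies, per-copy assignments are uniform by
  construction, so per-copy counts are estimates; only pooled copy-group
  quantities are interpretable — the profile functions pool by default.
* Ranking is by raw ratio with no error model; at low control counts the
  ranks of nearby ratios are not significant, which is why directed
  queries report the underlying window counts alongside.

# A worked run

```{r, eval = FALSE}
res <- run_paseq_pipeline(seed = 1)
res$map_summary                      # raw/mapped/percent/positions per run
head(res$ranked)                     # neither-category peaks by KD/ctrl ratio
res$leaders                          # Drosha-site leader calls
profile_window_fold(res$sno_profile, -3:-1, res$kd, res$ctrl)  # snoRNA trim
res$a0_fold                          # 5'ETS A0 window fold
res$r2$r2; res$histogram$frac_within_twofold
```
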