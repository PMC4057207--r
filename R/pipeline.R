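# pipeline: simulate -> demultiplex -> orient -> map -> sites -> peaks -> diff

#' Run the full PA-seq surveillance pipeline on simulated data
#'
#' Builds a toy genome with planted surveillance targets, simulates a
#' multiplexed two-condition sequencing run, demultiplexes and orients the
#' reads, maps them, tallies and filters adenylation sites, calls peaks on
#' the knockdown sample, and runs the differential layer: peak
#' categorization and ranking, the miRNA 5'-leader scan, snoRNA 3'-end
#' offset profiles, the 5'ETS A0 window fold, per-gene modal poly(A) sites
#' with the knockdown-vs-control R^2 and log2-ratio histogram.
#'
#' @param layout A [toy_layout()].
#' @param cfg A [sim_config()].
#' @param samples A [paseq_samples()] sheet (first `kd` and first `control`
#'   sample are used as the focal pair).
#' @param seed Master seed driving genome construction, read simulation,
#'   pooling and multimap assignment.
#' @param min_reads,bandwidth,window Stage parameters (site filter, peak
#'   kernel, mode-anchored window half-width).
#' @return A list with elements `genome`, `annotations`, `truth`, `reads`
#'   (pooled), `demux_counts`, `orient_counts`, `map_summary`, `hits`,
#'   `rejected`, `sites`, `peaks`, `ranked`, `leaders`, `sno_profile`,
#'   `a0_fold`, `modal`, `r2`, `histogram`, `kd`, `ctrl`.
#' @export
#' @examples
#' \donttest{
#' res <- run_paseq_pipeline(cfg = sim_config(n_read_pairs = 5000), seed = 1)
#' res$map_summary
#' }
run_paseq_pipeline <- function(layout = toy_layout(), cfg = sim_config(),
                               samples = paseq_samples(), seed = 1L,
                               min_reads = 5L, bandwidth = 5, window = 2L) {
  sim <- build_toy_genome(layout, seed = seed)
  cfg$seed <- as.integer(seed)

  runs <- lapply(seq_len(nrow(samples)), function(i)
    simulate_paseq_reads(sim$genome, sim$truth, cfg,
                         condition = samples$condition[i],
                         barcode = samples$barcode[i],
                         sample_id = samples$sample_id[i], stream = i))
  pooled <- pool_reads(runs, seed = sub_seed(seed, 1000L))

  dmx <- demultiplex(pooled$r1, pooled$r2,
                     setNames(samples$barcode, samples$sample_id))

  index <- build_kmer_index(sim$genome)
  hits_l <- list(); rej_l <- list(); raw_counts <- integer(0)
  orient_counts <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    ori <- orient_pairs(dmx$samples[[s]])
    orient_counts[[s]] <- c(oriented = nrow(ori$oriented),
                            rejected = nrow(ori$rejected))
    mp <- map_pairs(ori$oriented, index, repeats = sim$annotations$repeats,
                    seed = sub_seed(seed, 2000L + i))
    hits_l[[s]] <- mp$hits
    rej_l[[s]] <- mp$rejected
    raw_counts[s] <- nrow(dmx$samples[[s]])
  }
  hits <- data.table::rbindlist(hits_l, idcol = "sample_id")
  rejected <- data.table::rbindlist(rej_l, idcol = "sample_id")
  map_summary <- mapping_summary(raw_counts, hits)
  mapped_totals <- setNames(map_summary$mapped_reads, map_summary$sample_id)

  tbl <- tally_hits(hits)
  tbl <- apply_min_reads(tbl, min_reads)
  tbl <- normalize_rpm(tbl, mapped_totals)
  tbl <- filter_templated_a(tbl, sim$genome)

  kd <- samples$sample_id[samples$condition == "kd"][1]
  ctrl <- samples$sample_id[samples$condition == "control"][1]

  peaks <- call_peaks(tbl, kd, bandwidth = bandwidth, window = window)
  peaks <- categorize_peaks(peaks, sim$annotations$genes,
                            sim$annotations$repeats)
  ranked <- rank_neither(peaks, kd, ctrl)

  leaders <- mirna_leader_scan(tbl, sim$annotations$hairpins, sim$genome,
                               kd, ctrl, tol = window)
  sno_profile <- positional_profile(tbl, sim$annotations$snornas)
  a0 <- sim$annotations$rrna_sites[sim$annotations$rrna_sites$site == "A0", ]
  a0_fold <- {
    kdr <- window_raw(tbl, a0$contig, a0$strand, a0$pos, window, kd)
    ctr <- window_raw(tbl, a0$contig, a0$strand, a0$pos, window, ctrl)
    list(kd_reads = kdr, ctrl_reads = ctr,
         fold = if (ctr > 0) kdr / ctr else NA_real_)
  }

  modal <- refseq_modal_sites(tbl, sim$annotations$genes, min_modal = min_reads)
  both <- modal[modal[[paste0("pass_", kd)]] & modal[[paste0("pass_", ctrl)]]]
  r2 <- if (nrow(both) >= 3)
    scatter_r2(both[[paste0("rpm_", kd)]], both[[paste0("rpm_", ctrl)]])
  else NULL
  hist <- log2_histogram(log2(both[[paste0("rpm_", kd)]] /
                                both[[paste0("rpm_", ctrl)]]))

  list(genome = sim$genome, annotations = sim$annotations, truth = sim$truth,
       reads = pooled, demux_counts = dmx$counts,
       orient_counts = orient_counts, map_summary = map_summary,
       hits = hits, rejected = rejected, sites = tbl, peaks = peaks,
       ranked = ranked, leaders = leaders, sno_profile = sno_profile,
       a0_fold = a0_fold, modal = modal, r2 = r2, histogram = hist,
       kd = kd, ctrl = ctrl)
}
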