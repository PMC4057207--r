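# independent oracles and shared fixtures for the test suite

# Brute-force enumeration of read placements with <= max_mm substitutions,
# via Biostrings::matchPattern (independent of the package's k-mer scan).
brute_candidates <- function(seq, genome, max_mm = 2L) {
  rows <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$contig, out$start), , drop = FALSE]
}

# Independent templated-A rule: character-vector computation with rle(),
# distinct from the package's regex route.
oracle_a_flag <- function(window_chars, target = "A", run_len = 6L,
                          window_hits = 15L) {
  hit <- window_chars == target
  r <- rle(hit)
  max_run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  max_run >= run_len || sum(hit) >= window_hits
}

# Monte-Carlo interval for an observed KD/control window read ratio under
# the simulator's multinomial sampling design.  `probs` defaults to a
# two-sided 95% interval; joint assertions over m folds should pass
# Bonferroni-corrected probabilities (0.05/m split two-sided) so the family
# of checks is simultaneously a 95% interval.
mc_ratio_interval <- function(n_pairs, w_site_ctrl, w_tot_ctrl,
                              w_site_kd, w_tot_kd, nsim = 50000, seed = 99,
                              probs = c(0.025, 0.975)) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  kc <- rbinom(nsim, n_pairs, w_site_ctrl / w_tot_ctrl)
  kk <- rbinom(nsim, n_pairs, w_site_kd / w_tot_kd)
  r <- kk / pmax(kc, 1)
  stats::quantile(r, probs, names = FALSE)
}

# control-condition / kd-condition total truth weights for a truth table
truth_weights <- function(truth) {
  c(ctrl = sum(truth$abundance_control),
    kd = sum(truth$abundance_control * truth$fold_change_kd))
}

# small shared simulation so several test files can reuse one build
small_layout <- function() {
  toy_layout(genome_length = 30000L, n_genes = 6L, gene_abundance = 400)
}
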