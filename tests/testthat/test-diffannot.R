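# diffannot: modal sites, R2, histogram, categorization, ranking, features

site_row <- function(pos, raw, sample = "kd", strand = "+", contig = "c1",
                     rpm = NA_real_, below = FALSE, tmpl = FALSE) {
  data.table::data.table(contig = contig, strand = strand,
                         pos = as.integer(pos), sample_id = sample,
                         raw = as.integer(raw), rpm = rpm,
                         below_min_reads = below, templated_a = tmpl)
}

test_that("modal poly(A) sites respect the gene-end window and thresholds", {
  genes <- data.frame(contig = "c1", strand = "+", gene_id = "g1",
                      end3 = 1000L)
  tbl <- rbind(site_row(1000, 20), site_row(1000, 18, sample = "ctrl"),
               site_row(1051, 500), site_row(1051, 500, sample = "ctrl"))
  m <- refseq_modal_sites(tbl, genes)
  # the site at end+51 is outside the +/-50 window despite more reads
  expect_equal(m$modal_pos, 1000)
  expect_equal(m$raw_kd, 20)
  expect_true(m$pass_kd)
  # modal raw below five in a sample -> not passing there
  tbl2 <- rbind(site_row(1000, 20), site_row(1000, 4, sample = "ctrl"))
  m2 <- refseq_modal_sites(tbl2, genes)
  expect_true(m2$pass_kd)
  expect_false(m2$pass_ctrl)
  # tie at equal pooled counts resolves to the position nearest the end
  tbl3 <- rbind(site_row(c(995, 1000), c(10, 10)))
  expect_equal(refseq_modal_sites(tbl3, genes)$modal_pos, 1000)
  expect_warning(
    refseq_modal_sites(tbl, data.frame(contig = "c1", strand = "+",
                                       gene_id = "gx", end3 = NA)),
    "skipped")
})

test_that("R2 is the squared correlation of log signals", {
  expect_equal(scatter_r2(c(1, 2, 3, 4), c(1, 2, 3, 4))$r2, 1)
  r <- scatter_r2(c(1, 10, 100), c(100, 10, 1))
  expect_equal(r$r2, 1, tolerance = 1e-6)
  expect_equal(r$slope_sign, -1)    # anti-correlation is flagged, not hidden
  expect_error(scatter_r2(c(1, 2), c(1, 2)), "fewer than 3")
  # zero-signal genes are excluded and counted
  r2 <- scatter_r2(c(0, 1, 2, 3), c(5, 1, 2, 3))
  expect_equal(r2$n_used, 3)
  expect_equal(r2$n_excluded, 1)
})

test_that("log2 histogram bins follow the 0.2/0.4 edge convention", {
  h <- log2_histogram(c(0.1, -0.15, 0.2, 0.5, 0.61, -0.5, 2.5, NA, Inf))
  hist <- h$histogram
  get_n <- function(lab) hist$n[hist$bin_label == lab]
  expect_equal(get_n("0"), 3L)       # 0.1, -0.15 and the +0.2 boundary
  expect_equal(get_n("+0.6"), 1L)    # 0.5
  expect_equal(get_n("+1.0"), 1L)    # 0.61
  expect_equal(get_n("-0.6"), 1L)    # -0.5
  expect_equal(get_n("+2.6"), 1L)    # 2.5 -> outer edge 0.2 + 0.4*6
  expect_equal(h$n_undefined, 2L)
  expect_equal(h$frac_within_twofold, 6 / 7)
})

test_that("peak categorization follows the refseq > repeat > neither precedence", {
  genes <- data.frame(contig = "c1", strand = "+", gene_id = "g1",
                      end3 = 1000L)
  reps <- data.frame(contig = "c1", start = 5000L, end = 5500L)
  pk <- data.table::data.table(
    cluster_id = c("p1", "p2", "p3", "p4"), contig = "c1",
    strand = c("+", "+", "+", "-"),
    mode_pos = c(1010L, 5100L, 7000L, 1000L))
  out <- categorize_peaks(pk, genes, reps)
  # mode at a gene end (matching strand) -> refseq; wrong strand -> not
  expect_equal(out$category, c("refseq_pa", "repeat", "neither", "neither"))
})

test_that("neither-category ranking reproduces printed window-sum ratios", {
  pk <- data.table::data.table(
    cluster_id = sprintf("p%d", 1:5), contig = "c1", strand = "+",
    mode_pos = 1:5 * 100L, category = c("neither", "neither", "neither",
                                        "neither", "refseq_pa"),
    window_kd = c(250L, 332L, 40L, 10L, 999L),
    window_ctrl = c(4L, 43L, 6L, 0L, 1L))
  r <- rank_neither(pk, "kd", "ctrl")
  # control-zero peaks rank first as N.D., then finite ratios descending
  expect_equal(r$cluster_id, c("p4", "p1", "p2", "p3"))
  expect_equal(r$ratio_label[1], "N.D.")
  expect_equal(r$ratio[2], 62.5)
  expect_equal(round(r$ratio[3], 2), 7.72)
  expect_equal(round(r$ratio[4], 2), 6.67)
  # ratio/record consistency: ratio * ctrl == kd exactly
  fin <- r[!is.na(ratio)]
  expect_equal(fin$ratio * fin$ctrl_reads, as.numeric(fin$kd_reads))
  expect_equal(nrow(rank_neither(pk, "kd", "ctrl", exclude_nd = TRUE)), 3)
})

test_that("the leader scan anchors at the Drosha site on either strand", {
  genome <- c(c1 = strrep("ACGT", 600))
  hp <- data.frame(contig = "c1", start = c(500L, 1500L), end = c(559L, 1559L),
                   strand = c("+", "-"), mirna = c("mirP", "mirM"),
                   cluster_id = "cl1")
  # plus-strand hairpin: drosha = start - 1; minus: end + 1
  tbl <- rbind(site_row(499, 60), site_row(499, 2, sample = "ctrl"),
               site_row(1560, 30, strand = "-"),
               site_row(502, 7))     # inside hairpin, outside +/-2 window
  sc <- mirna_leader_scan(tbl, hp, genome, kd = "kd", ctrl = "ctrl")
  expect_equal(sc$drosha_site, c(499L, 1560L))
  expect_equal(sc$modal_pos, c(499L, 1560L))
  expect_equal(sc$kd_reads, c(60L, 30L))
  expect_equal(sc$ctrl_reads, c(2L, 0L))
  expect_equal(sc$ratio[1], 30)
  expect_equal(sc$ratio_label[2], "N.D.")
  # a hairpin with no reads in either sample is suppressed without --all
  hp2 <- rbind(hp, data.frame(contig = "c1", start = 2200L, end = 2259L,
                              strand = "+", mirna = "mirZ",
                              cluster_id = "cl2"))
  expect_equal(nrow(mirna_leader_scan(tbl, hp2, genome, "kd", "ctrl")), 2)
  expect_equal(nrow(mirna_leader_scan(tbl, hp2, genome, "kd", "ctrl",
                                      all = TRUE)), 3)
  # control-only signal reports a ratio below one, not an accumulation
  tbl2 <- rbind(site_row(499, 2), site_row(499, 8, sample = "ctrl"))
  sc2 <- mirna_leader_scan(tbl2, hp, genome, "kd", "ctrl")
  expect_lt(sc2$ratio[1], 1)
  # hairpin at the contig edge is skipped with a warning
  hp3 <- data.frame(contig = "c1", start = 1L, end = 60L, strand = "+",
                    mirna = "mirE", cluster_id = "cl3")
  expect_warning(mirna_leader_scan(tbl, hp3, genome, "kd", "ctrl"),
                 "edge")
})

test_that("positional profiles use strand-aware offsets pooled over copies", {
  feats <- data.frame(contig = "c1", start = c(100L, 900L),
                      end = c(313L, 1113L), strand = "+",
                      copy_group = "U3")
  tbl <- rbind(site_row(313, 10), site_row(310, 6),
               site_row(1113, 14), site_row(1110, 2),
               site_row(315, 3))
  pr <- positional_profile(tbl, feats, offset_range = c(-5L, 3L))
  expect_equal(pr[offset == 0]$raw, 24L)      # pooled 10 + 14
  expect_equal(pr[offset == -3]$raw, 8L)      # pooled 6 + 2
  expect_equal(pr[offset == 2]$raw, 3L)
  # minus-strand arithmetic: genomic end3 - k maps to offset +k
  featm <- data.frame(contig = "c1", start = 2000L, end = 2029L,
                      strand = "-", copy_group = "M")
  tblm <- rbind(site_row(1995, 9, strand = "-"),
                site_row(2003, 4, strand = "-"))
  prm <- positional_profile(tblm, featm, offset_range = c(-5L, 6L))
  expect_equal(prm[offset == 5]$raw, 9L)      # 2000 - 1995 = +5 (past end)
  expect_equal(prm[offset == -3]$raw, 4L)     # inside the feature
  # cumulative window fold
  tblk <- rbind(site_row(313, 90), site_row(310, 45),
                site_row(313, 10, sample = "ctrl"),
                site_row(310, 5, sample = "ctrl"))
  prk <- positional_profile(tblk, feats[1, ], offset_range = c(-5L, 0L))
  f <- profile_window_fold(prk, -3:0, "kd", "ctrl")
  expect_equal(f$fold, 9)
})

test_that("the 5'-mate check distinguishes internal fragments from read-through", {
  hits <- data.table::data.table(
    contig = "c1", strand = "+", pa_pos = c(300L, 300L, 298L, 301L),
    m5_start = c(120L, 150L, 90L, 180L), m5_end = c(155L, 185L, 125L, 215L))
  qc <- five_prime_mate_qc(hits, "c1", 100L, 313L, "+")
  expect_equal(qc$fraction, 0.75)             # one mate starts upstream
  expect_equal(qc$n_hits, 4L)
  qc0 <- five_prime_mate_qc(hits, "c1", 5000L, 5300L, "+")
  expect_true(is.na(qc0$fraction))
})
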