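# synthetic-data module: genome construction, library chemistry, determinism

test_that("genome construction is deterministic and plants the full layout", {
  sim1 <- build_toy_genome(toy_layout(), seed = 1)
  sim2 <- build_toy_genome(toy_layout(), seed = 1)
  expect_identical(sim1, sim2)
  sim3 <- build_toy_genome(toy_layout(), seed = 2)
  expect_false(identical(sim1$genome, sim3$genome))

  ann <- sim1$annotations
  expect_true(nrow(ann$genes) >= 1)
  expect_setequal(ann$rrna_sites$site, c("A_prime", "A0", "site1"))
  expect_gte(nrow(ann$snornas), 2)
  expect_gte(nrow(ann$hairpins), 2)
  expect_gte(nrow(ann$repeats), 1)
  expect_true(all(c("mRNA_PA", "ETS_A0", "snoRNA_offset", "mirna_leader",
                    "internal_priming_trap") %in% sim1$truth$category))
  # all characters ACGT, intervals in bounds
  expect_true(grepl("^[ACGT]+$", sim1$genome[[1]]))
  expect_true(all(ann$genes$end <= nchar(sim1$genome[[1]])))

  # FASTA round trip is byte-stable under the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(sim1$genome, f1)
  write_genome_fasta(sim2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_genome_fasta(f1), sim1$genome)
})

test_that("identical tandem snoRNA copies extract identical subsequences", {
  sim <- build_toy_genome(toy_layout(n_sno_copies = 4L), seed = 3)
  sn <- sim$annotations$snornas
  expect_equal(nrow(sn), 4)
  seqs <- substring(sim$genome[[1]], sn$start, sn$end)
  expect_length(unique(seqs), 1)
})

test_that("an infeasible layout raises a sizing error", {
  expect_error(build_toy_genome(toy_layout(genome_length = 1000L), seed = 1),
               "exceeds genome length")
})

test_that("simulator config and sample sheet validation reject bad input", {
  expect_error(sim_config(frag_min = 50), "fragment-size")
  expect_error(sim_config(frag_min = 200, frag_max = 1500), "fragment-size")
  expect_error(sim_config(read_len = 200, frag_min = 150), "read length")
  expect_error(paseq_samples(barcode = c("ACGTA", "ACGTA")), "uplicate")
  expect_error(paseq_samples(barcode = c("ACGT", "TGCAT")), "5-mer")
})

test_that("noiseless reads have the TTT tag adjacent to the terminal residue", {
  sim <- build_toy_genome(small_layout(), seed = 5)
  cfg <- sim_config(n_read_pairs = 2000, error_rate = 0, seed = 5)
  rr <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "control",
                             barcode = "ACGTA", sample_id = "s", stream = 1)
  # conservation: emitted pairs == configured pairs
  expect_length(rr$r1, cfg$n_read_pairs)
  expect_length(rr$r2, cfg$n_read_pairs)

  m1 <- substr(rr$r1, 6, nchar(rr$r1))   # strip barcode
  tag1 <- startsWith(m1, "TTT")
  tag2 <- startsWith(rr$r2, "TTT")
  # exactly one mate is tagged for every pair (terminal residues are non-A,
  # and with zero errors the 5' mate can still start with TTT by template
  # chance, but the tagged mate is always tagged)
  expect_true(all(tag1 | tag2))
  threep <- ifelse(tag1 & !tag2, substr(m1, 4, nchar(m1)),
                   ifelse(tag2 & !tag1, substr(rr$r2, 4, nchar(rr$r2)), NA))
  ok <- !is.na(threep)
  # first templated base is the complement of a non-A terminal residue,
  # hence never T: the tag is exactly three T long
  expect_false(any(startsWith(threep[ok], "T")))

  # templated segment maps back to the truth position, strand-aware
  tt <- sim$truth; rownames(tt) <- tt$site_id
  site <- tt[rr$truth_site[ok], ]
  tlen <- cfg$read_len - 3L
  expect_seq <- ifelse(
    site$strand == "+",
    revcomp(substring(sim$genome[site$contig], site$pos - tlen + 1, site$pos)),
    substring(sim$genome[site$contig], site$pos, site$pos + tlen - 1))
  expect_identical(unname(threep[ok]), unname(expect_seq))
})

test_that("read simulation is byte-deterministic under a fixed seed", {
  sim <- build_toy_genome(small_layout(), seed = 5)
  cfg <- sim_config(n_read_pairs = 1000, seed = 11)
  r1 <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "kd", "TGCAT", "k", 2)
  r2 <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "kd", "TGCAT", "k", 2)
  expect_identical(r1, r2)
  f1a <- tempfile(); f2a <- tempfile(); f1b <- tempfile(); f2b <- tempfile()
  write_fastq_pairs(r1, f1a, f2a)
  write_fastq_pairs(r2, f1b, f2b)
  expect_identical(readLines(f1a), readLines(f1b))
  back <- read_fastq_pairs(f1a, f2a)
  expect_identical(unname(back$r1), unname(r1$r1))
  # a different substream gives different reads
  r3 <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "kd", "TGCAT", "k", 3)
  expect_false(identical(r1$r1, r3$r1))
})

test_that("planted knockdown fold changes are recovered within binomial error", {
  sim <- build_toy_genome(small_layout(), seed = 5)
  cfg <- sim_config(n_read_pairs = 50000, error_rate = 0, seed = 13)
  ctl <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "control",
                              "ACGTA", "c", 1)
  kd <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "kd",
                             "TGCAT", "k", 2)
  tr <- sim$truth
  lead <- tr[tr$category == "mirna_leader", ][1, ]
  w <- truth_weights(tr)
  nc <- sum(ctl$truth_site == lead$site_id)
  nk <- sum(kd$truth_site == lead$site_id)
  iv <- mc_ratio_interval(cfg$n_read_pairs,
                          lead$abundance_control, w["ctrl"],
                          lead$abundance_control * lead$fold_change_kd,
                          w["kd"])
  expect_gte(nk / max(nc, 1), iv[1])
  expect_lte(nk / max(nc, 1), iv[2])
})

test_that("internal-priming trap reads end adjacent to a genomic A-run", {
  sim <- build_toy_genome(small_layout(), seed = 5)
  cfg <- sim_config(n_read_pairs = 5000, error_rate = 0, seed = 17)
  rr <- simulate_paseq_reads(sim$genome, sim$truth, cfg, "control",
                             "ACGTA", "c", 1)
  tr <- sim$truth[sim$truth$category == "internal_priming_trap", ]
  expect_gt(sum(rr$truth_site %in% tr$site_id), 0)
  for (i in seq_len(nrow(tr))) {
    down <- substring(sim$genome[tr$contig[i]], tr$pos[i] + 1, tr$pos[i] + 20)
    ch <- strsplit(down, "")[[1]]
    expect_true(oracle_a_flag(ch))
  }
})

test_that("annotation writers round-trip through plain-text formats", {
  sim <- build_toy_genome(small_layout(), seed = 5)
  d <- tempfile()
  write_annotation_set(sim$annotations, sim$truth, d)
  expect_true(all(file.exists(file.path(
    d, c("genes.bed", "repeats.bed", "snorna.bed", "hairpins.gff",
         "rrna_sites.tsv", "truth.tsv")))))
  genes <- read.table(file.path(d, "genes.bed"), sep = "\t")
  # BED is 0-based half-open on disk
  expect_equal(genes$V2, sim$annotations$genes$start - 1L)
  expect_equal(genes$V3, sim$annotations$genes$end)
  truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(truth$pos, sim$truth$pos)
  gff <- readLines(file.path(d, "hairpins.gff"))
  expect_identical(gff[1], "##gff-version 3")
})
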