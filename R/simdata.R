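# simdata: toy genome with planted surveillance targets + PA-seq read simulator

#' Simulation configuration for PA-seq libraries
#'
#' Parameters of the simulated library chemistry.  Defaults emulate the PA-seq
#' protocol: paired-end reads where the 3'-end mate opens with a three-T tag
#' (left by USER cleavage of the dT/deoxyU/TTTVN reverse-transcription primer)
#' immediately adjacent to the complement of the transcript's 3'-terminal
#' residue, a 5-nt sample barcode opening read 1, and gel size selection of
#' the library in the low-hundreds of base pairs.
#'
#' @param n_read_pairs Number of read pairs emitted per sample.
#' @param read_len Length of each mate's payload (after the read-1 barcode).
#' @param frag_min,frag_max Size-selection window for cDNA fragments, in
#'   bases; must lie within \[100, 1000\] and `read_len <= frag_min`.
#' @param error_rate Per-base substitution error probability.
#' @param qual_char Constant Phred+33 quality character written to FASTQ.
#' @param tag 3'-mate tag sequence; the chemistry leaves exactly three T's.
#' @param seed Master seed; per-sample substreams are derived from it.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_read_pairs = 1000, seed = 7)
sim_config <- function(n_read_pairs = 2e5, read_len = 36, frag_min = 150,
                       frag_max = 400, error_rate = 0.001, qual_char = "I",
                       tag = "TTT", seed = 1L) {
  if (frag_min < 100 || frag_max > 1000 || frag_min > frag_max)
    stop_config("fragment-size range must lie within [100, 1000]")
  if (read_len > frag_min)
    stop_config("read length must not exceed the minimum fragment size")
  if (error_rate < 0 || error_rate >= 1)
    stop_config("error_rate must be in [0, 1)")
  if (!identical(tag, "TTT"))
    stop_config("the library chemistry leaves exactly a TTT tag")
  structure(list(n_read_pairs = as.integer(n_read_pairs),
                 read_len = as.integer(read_len),
                 frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max),
                 error_rate = error_rate, qual_char = qual_char,
                 tag = tag, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample sheet for a two-condition PA-seq run
#'
#' @param sample_id Sample names.
#' @param condition One of `"control"` or `"kd"` per sample.
#' @param barcode Distinct 5-mer barcodes, matched exactly at the first five
#'   bases of read 1 during demultiplexing.
#' @return A data.frame with one row per sample.
#' @export
paseq_samples <- function(sample_id = c("ctrl1", "kd1"),
                          condition = c("control", "kd"),
                          barcode = c("ACGTA", "TGCAT")) {
  if (any(nchar(barcode) != 5L)) stop_config("barcodes must be 5-mers")
  if (anyDuplicated(barcode)) stop_config("duplicate sample barcodes")
  if (!all(condition %in% c("control", "kd")))
    stop_config("condition must be 'control' or 'kd'")
  data.frame(sample_id = sample_id, condition = condition, barcode = barcode,
             stringsAsFactors = FALSE)
}

#' Feature layout for the toy genome
#'
#' Declares how many features of each category are planted and their expected
#' read abundances (control condition) and knockdown fold changes.  Defaults
#' are the package's standard study conditions: a null mRNA background (no
#' planted mRNA fold change), pri-miRNA 5' leaders accumulating 60-fold in the
#' knockdown, snoRNA species over-trimmed by 1-3 nt accumulating 9-fold,
#' an rRNA 5'ETS fragment ending at the A0 processing site accumulating
#' 8-fold, internal-priming traps over genomic A-runs, a planted site inside
#' a repeat interval, and null non-coding sites with no fold change.
#'
#' @param genome_length Total contig length in bases.
#' @param contig Contig name.
#' @param n_genes Number of protein-coding-like genes with canonical poly(A)
#'   sites.
#' @param gene_len Gene length (bases).
#' @param gene_abundance Expected control reads weight per gene poly(A) site.
#' @param n_sno_copies Identical tandem snoRNA copies (one copy group).
#' @param sno_len Mature snoRNA length; 214 matches U3B.
#' @param sno_spacing Start-to-start spacing between tandem copies.
#' @param sno_end_ab,sno_trim_ab,sno_plus2_ab Per-copy abundance weights for
#'   species ending at the annotated 3' end (offset 0), at each of offsets
#'   -1..-3 (over-trimmed), and at offset +2.
#' @param sno_trim_fold Knockdown fold change of the over-trimmed species.
#' @param a0_ab,a0_fold Abundance and knockdown fold of the 5'ETS fragment
#'   adenylated at the A0 processing site.
#' @param leader_ab Control abundance weight of each planted miRNA 5' leader
#'   (one per miRNA cluster).
#' @param leader_fold Knockdown fold change of planted 5' leaders.
#' @param host_ab Abundance of each miRNA host gene's own poly(A) site.
#' @param trap_ab Abundance of reads internally primed at each planted
#'   genomic A-run trap.
#' @param repeat_site_ab Abundance of the site planted inside a repeat.
#' @param ncnull_ab Abundance of each planted null non-coding site.
#' @param n_multicopy Copies of an optional high-copy (12x) element whose
#'   reads match too many positions to be used; 0 disables it.
#' @param margin Spacing between feature blocks (bases), sized so that read
#'   fragments never extend into a neighbouring feature.
#' @return A list of class `toy_layout`.
#' @export
toy_layout <- function(genome_length = 60000L, contig = "chrS",
                       n_genes = 20L, gene_len = 900L, gene_abundance = 2000,
                       n_sno_copies = 4L, sno_len = 214L, sno_spacing = 1200L,
                       sno_end_ab = 40, sno_trim_ab = 8, sno_plus2_ab = 5,
                       sno_trim_fold = 9, a0_ab = 25, a0_fold = 8,
                       leader_ab = c(4, 6), leader_fold = 60, host_ab = 100,
                       trap_ab = 60, repeat_site_ab = 40, ncnull_ab = 50,
                       n_multicopy = 0L, margin = 650L) {
  structure(as.list(environment()), class = "toy_layout")
}

# draw a 20-mer that can never trip the templated-A filter: at most 2 A's,
# never adjacent, and positions 1-3 A-free (so sites up to +2 away stay safe)
apoor20 <- function() {
  w <- sample(c("C", "G", "T"), 20, replace = TRUE)
  na <- sample(0:2, 1)
  if (na > 0) {
    ok <- 4:20
    p1 <- sample(ok, 1)
    w[p1] <- "A"
    if (na == 2) {
      ok <- setdiff(ok, (p1 - 1):(p1 + 1))
      w[sample(ok, 1)] <- "A"
    }
  }
  w
}

rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = c(.2, .3, .3, .2))
}

#' Build a toy genome with planted surveillance targets
#'
#' Constructs a random genome and plants, per the layout: protein-coding-like
#' genes with canonical poly(A) sites; an rRNA unit carrying the 5'ETS
#' processing sites A', A0 and the 18S junction; identical tandem snoRNA
#' copies (a multimapping copy group) with planted 3'-end offset species;
#' miRNA clusters inside host transcripts whose first hairpin has a planted
#' adenylated 5' leader ending exactly at the Drosha cleavage site; repeat
#' intervals (one harbouring a planted site); internal-priming traps (genomic
#' A-runs downstream of a fake site); and null non-coding sites.  Every
#' planted true site is given a non-A 3'-terminal base and an A-poor
#' downstream 20-mer, so only the traps trip the templated-adenosine filter.
#'
#' Coordinates are 1-based and inclusive throughout; annotated 3' ends are the
#' last transcribed base on the feature's strand.
#'
#' @param layout A [toy_layout()].
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @return A list with elements `genome` (named character vector of contig
#'   sequences), `annotations` (list of data.frames: `genes`, `repeats`,
#'   `snornas`, `hairpins`, `rrna_sites`) and `truth` (the truth table:
#'   one row per planted site with `site_id`, `contig`, `strand`, `pos`,
#'   `category`, `abundance_control`, `fold_change_kd`, `upstream_limit`,
#'   `feature_id`, `copy_group`).
#' @export
#' @examples
#' sim <- build_toy_genome(toy_layout(n_genes = 2), seed = 1)
#' names(sim$annotations)
build_toy_genome <- function(layout = toy_layout(), seed = 1L) {
  stopifnot(inherits(layout, "toy_layout"))
  with_seed(seed, {
    L <- as.integer(layout$genome_length)
    g <- rand_bases(L)
    margin <- as.integer(layout$margin)
    cur <- margin + 1L

    alloc <- function(width) {
      if (cur + width + margin > L)
        stop_config("layout exceeds genome length: need more than ",
                    L, " bases")
      s <- cur
      cur <<- cur + as.integer(width) + margin
      s
    }

    genes <- list(); repeats <- list(); snornas <- list()
    hairpins <- list(); truth <- list()

    # plant a true adenylation site: non-A terminal base, A-poor 20-mer
    # downstream in transcript orientation (the internal-priming filter's
    # window); optionally with caller-supplied content so identical tandem
    # copies stay identical
    plant_site <- function(pos, strand, terminal = NULL, win = NULL) {
      if (is.null(terminal)) terminal <- sample(c("C", "G"), 1)
      if (is.null(win)) win <- apoor20()
      g[pos] <<- if (strand == "+") terminal else comp_chars(terminal)
      if (strand == "+") {
        g[(pos + 1L):(pos + 20L)] <<- win
      } else {
        g[(pos - 20L):(pos - 1L)] <<- rev(comp_chars(win))
      }
      invisible(NULL)
    }
    add_truth <- function(site_id, strand, pos, category, ab, fold,
                          upstream_limit, feature_id, copy_group = NA) {
      truth[[length(truth) + 1L]] <<- data.frame(
        site_id = site_id, contig = layout$contig, strand = strand,
        pos = as.integer(pos), category = category,
        abundance_control = ab, fold_change_kd = fold,
        upstream_limit = as.integer(upstream_limit),
        feature_id = feature_id, copy_group = copy_group,
        stringsAsFactors = FALSE)
    }

    ## genes with canonical poly(A) sites (alternating strands; null fold)
    for (i in seq_len(layout$n_genes)) {
      s <- alloc(layout$gene_len)
      e <- s + layout$gene_len - 1L
      strand <- if (i %% 2L == 1L) "+" else "-"
      end3 <- if (strand == "+") e else s
      up <- if (strand == "+") s else e
      genes[[i]] <- data.frame(contig = layout$contig, start = s, end = e,
                               strand = strand,
                               gene_id = sprintf("gene%02d", i),
                               end3 = end3, stringsAsFactors = FALSE)
      plant_site(end3, strand)
      add_truth(sprintf("gene%02d_pa", i), strand, end3, "mRNA_PA",
                layout$gene_abundance, 1, up, sprintf("gene%02d", i))
    }

    ## rRNA unit: 5'ETS processing sites A', A0, 18S junction (site1)
    rs <- alloc(2600L)
    a_prime <- rs + 500L; a0 <- rs + 1300L; site1 <- rs + 2200L
    rrna_sites <- data.frame(
      site = c("A_prime", "A0", "site1"), contig = layout$contig,
      strand = "+", pos = c(a_prime, a0, site1), stringsAsFactors = FALSE)
    plant_site(a0, "+")
    add_truth("ets_a0", "+", a0, "ETS_A0", layout$a0_ab, layout$a0_fold,
              a_prime, "rRNA_5ETS")

    ## identical tandem snoRNA copies with planted 3'-offset species
    n_sno <- layout$n_sno_copies
    sno_seq <- c(rand_bases(layout$sno_len - 30L),
                 sample(c("C", "G", "T"), 30L, replace = TRUE))
    sno_base <- alloc(n_sno * layout$sno_spacing)
    sno_starts <- sno_base + (seq_len(n_sno) - 1L) * layout$sno_spacing
    sno_offsets <- c(0L, -1L, -2L, -3L, 2L)
    sno_ab <- c(layout$sno_end_ab, rep(layout$sno_trim_ab, 3), layout$sno_plus2_ab)
    sno_fold <- c(1, rep(layout$sno_trim_fold, 3), 1)
    # shared per-offset terminal/window content keeps the copies identical
    off_term <- replicate(length(sno_offsets), sample(c("C", "G"), 1))
    off_win <- replicate(length(sno_offsets), apoor20(), simplify = FALSE)
    for (ci in seq_len(n_sno)) {
      s <- sno_starts[ci]; e <- s + layout$sno_len - 1L
      g[s:e] <- sno_seq
      snornas[[ci]] <- data.frame(contig = layout$contig, start = s, end = e,
                                  strand = "+",
                                  sno_id = sprintf("U3B.%d", ci),
                                  copy_group = "U3B", stringsAsFactors = FALSE)
      for (oi in seq_along(sno_offsets)) {
        p <- e + sno_offsets[oi]
        plant_site(p, "+", terminal = off_term[oi], win = off_win[[oi]])
        add_truth(sprintf("U3B.%d_off%+d", ci, sno_offsets[oi]), "+", p,
                  "snoRNA_offset", sno_ab[oi], sno_fold[oi], s,
                  sprintf("U3B.%d", ci), "U3B")
      }
      # copy content was rewritten by planting; refresh the shared sequence
      # from the first copy so later copies stay bit-identical
      if (ci == 1L) sno_seq <- g[s:e]
    }

    ## miRNA clusters inside host transcripts (one planted leader each)
    n_clusters <- length(layout$leader_ab)
    for (mi in seq_len(n_clusters)) {
      strand <- if (mi %% 2L == 1L) "-" else "+"
      host_len <- if (strand == "-") 1500L else 1200L
      s <- alloc(host_len); e <- s + host_len - 1L
      gid <- sprintf("mirhost%d", mi)
      genes[[length(genes) + 1L]] <- data.frame(
        contig = layout$contig, start = s, end = e, strand = strand,
        gene_id = gid, end3 = if (strand == "+") e else s,
        stringsAsFactors = FALSE)
      plant_site(if (strand == "+") e else s, strand)
      add_truth(paste0(gid, "_pa"), strand, if (strand == "+") e else s,
                "mRNA_PA", layout$host_ab, 1,
                if (strand == "+") s else e, gid)
      if (strand == "-") {
        # two hairpins; hairpin 1 is 5'-most in transcript orientation
        h1 <- c(s + 1100L, s + 1159L); h2 <- c(s + 850L, s + 909L)
        hp <- data.frame(contig = layout$contig,
                         start = c(h1[1], h2[1]), end = c(h1[2], h2[2]),
                         strand = strand,
                         mirna = sprintf("mir%d-%d", 300 + mi, 1:2),
                         cluster_id = sprintf("cluster%d", mi),
                         stringsAsFactors = FALSE)
        drosha <- h1[2] + 1L          # base immediately 5' of the hairpin
        leader_up <- e                # host 5' end
      } else {
        h1 <- c(s + 700L, s + 759L)
        hp <- data.frame(contig = layout$contig, start = h1[1], end = h1[2],
                         strand = strand,
                         mirna = sprintf("mir%d-1", 300 + mi),
                         cluster_id = sprintf("cluster%d", mi),
                         stringsAsFactors = FALSE)
        drosha <- h1[1] - 1L
        leader_up <- s
      }
      hairpins[[length(hairpins) + 1L]] <- hp
      plant_site(drosha, strand)
      add_truth(sprintf("%s_leader", hp$mirna[1]), strand, drosha,
                "mirna_leader", layout$leader_ab[mi], layout$leader_fold,
                leader_up, hp$mirna[1], hp$cluster_id[1])
    }

    ## repeat intervals; the first harbours a planted site
    for (ri in 1:2) {
      s <- alloc(500L); e <- s + 499L
      repeats[[ri]] <- data.frame(contig = layout$contig, start = s, end = e,
                                  repeat_id = sprintf("rep%d", ri),
                                  stringsAsFactors = FALSE)
      if (ri == 1L && layout$repeat_site_ab > 0) {
        p <- s + 450L
        plant_site(p, "+")
        add_truth("repeat_site", "+", p, "repeat_site",
                  layout$repeat_site_ab, 2, s, "rep1")
      }
    }

    ## internal-priming traps: fake sites over genomic A-runs
    trap_runs <- list(
      rep("A", 8L),                                     # >=6 continuous A
      c(rep("A", 5), "G", rep("A", 5), "G", rep("A", 5), "G", "A", "A"))
    for (ti in seq_along(trap_runs)) {
      s <- alloc(600L)
      p <- s + 520L
      g[p] <- sample(c("C", "G"), 1)                    # non-A terminal base
      run <- trap_runs[[ti]]
      g[(p + 1L):(p + length(run))] <- run
      # keep the rest of the 20-nt window A-free so trap 2 tests the
      # 15-of-20 branch without a >=6 run
      restlen <- 20L - length(run)
      if (restlen > 0)
        g[(p + length(run) + 1L):(p + 20L)] <-
          sample(c("C", "G", "T"), restlen, replace = TRUE)
      add_truth(sprintf("trap%d", ti), "+", p, "internal_priming_trap",
                layout$trap_ab, 1, s, sprintf("trap%d", ti))
    }

    ## null non-coding sites (the "neither"-category null controls)
    for (ni in 1:2) {
      s <- alloc(600L)
      strand <- if (ni == 1L) "+" else "-"
      p <- if (strand == "+") s + 520L else s + 80L
      up <- if (strand == "+") s else s + 599L
      plant_site(p, strand)
      add_truth(sprintf("ncnull%d", ni), strand, p, "ncRNA_null",
                layout$ncnull_ab, 1, up, sprintf("ncnull%d", ni))
    }

    ## optional 12-copy element (reads match >=10 positions -> discarded)
    if (layout$n_multicopy > 0) {
      nmc <- as.integer(layout$n_multicopy)
      el <- rand_bases(90L)
      el[80L] <- "C"
      base <- alloc(nmc * 200L)
      starts <- base + (seq_len(nmc) - 1L) * 200L
      for (s in starts) g[s:(s + 89L)] <- el
      add_truth("multicopy_site", "+", starts[1] + 79L, "multicopy",
                100, 1, starts[1], "multicopy")
    }

    annotations <- list(
      genes = do.call(rbind, genes),
      repeats = do.call(rbind, repeats),
      snornas = do.call(rbind, snornas),
      hairpins = do.call(rbind, hairpins),
      rrna_sites = rrna_sites)
    truth <- do.call(rbind, truth)
    list(genome = setNames(paste(g, collapse = ""), layout$contig),
         annotations = annotations, truth = truth)
  })
}

# substitute sequencing errors into a vector of equal-length reads
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  w <- nchar(seqs[1])
  k <- rbinom(length(seqs), w, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(k > 0L)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in sample.int(w, k[i])) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate one sample's PA-seq paired-end reads
#'
#' Draws `n_read_pairs` read pairs by multinomial sampling over the truth
#' table's site weights (`abundance_control`, multiplied by `fold_change_kd`
#' for the knockdown condition).  Each pair derives from a cDNA fragment of
#' the adenylated species ending at the site's genomic position `p`: the
#' 3'-end mate is `TTT` followed by the reverse complement of the template
#' ending at `p` (so the base after the tag is the complement of the
#' 3'-terminal residue), and the 5' mate reads inward from the fragment's
#' other end on the opposite strand.  Drawn fragment lengths are capped at
#' the species length (distance to `upstream_limit`), emulating
#' size-selection of short RNAs.  Read 1 opens with the sample barcode, and
#' the TTT-tagged mate is assigned to read 1 or read 2 at random, so
#' read preparation must detect it.  Internal-priming trap sites generate
#' reads by the same mechanism, i.e. apparent 3' ends adjacent to genomic
#' A-runs with no true adenylation event.
#'
#' @param genome Named character vector of contig sequences.
#' @param truth Truth table from [build_toy_genome()].
#' @param cfg A [sim_config()].
#' @param condition `"control"` or `"kd"`.
#' @param barcode 5-mer sample barcode.
#' @param sample_id Sample name used in read ids.
#' @param stream Integer substream index; reads are drawn from a
#'   deterministic substream of `cfg$seed` so multi-sample runs are
#'   reproducible sample by sample.
#' @return A list of class `paseq_reads` with `ids`, `r1`, `r2`, `qual1`,
#'   `qual2`, `truth_site` (ground-truth site id per pair), `sample_id`,
#'   `condition`.
#' @export
simulate_paseq_reads <- function(genome, truth, cfg = sim_config(),
                                 condition = c("control", "kd"),
                                 barcode = "ACGTA", sample_id = "s1",
                                 stream = 1L) {
  condition <- match.arg(condition)
  if (nchar(barcode) != 5L) stop_config("barcode must be a 5-mer")
  with_seed(sub_seed(cfg$seed, stream), {
    w <- truth$abundance_control *
      (if (condition == "kd") truth$fold_change_kd else 1)
    n <- cfg$n_read_pairs
    counts <- as.vector(rmultinom(1, n, w / sum(w)))
    si <- rep(seq_len(nrow(truth)), counts)
    si <- sample(si)                       # shuffle read order
    pos <- truth$pos[si]
    strand <- truth$strand[si]
    ctg <- truth$contig[si]
    gseq <- genome[ctg]
    up <- truth$upstream_limit[si]
    avail <- ifelse(strand == "+", pos - up + 1L, up - pos + 1L)
    flen <- pmax(cfg$read_len,
                 pmin(floor(runif(n, cfg$frag_min, cfg$frag_max + 1)), avail))
    tlen <- cfg$read_len - 3L
    # 3'-end mate: TTT + revcomp(template ending at pos)
    s3 <- ifelse(strand == "+",
                 revcomp(substring(gseq, pos - tlen + 1L, pos)),
                 substring(gseq, pos, pos + tlen - 1L))
    payload3 <- paste0("TTT", s3)
    # 5' mate: read_len bases inward from the fragment's far end
    m5 <- ifelse(strand == "+",
                 substring(gseq, pos - flen + 1L, pos - flen + cfg$read_len),
                 revcomp(substring(gseq, pos + flen - cfg$read_len, pos + flen - 1L)))
    tag_first <- runif(n) < 0.5
    r1 <- paste0(barcode, ifelse(tag_first, payload3, m5))
    r2 <- ifelse(tag_first, m5, payload3)
    # substitution errors over the full reads, barcode and tag included
    r1 <- setNames(apply_seq_errors(r1, cfg$error_rate), NULL)
    r2 <- setNames(apply_seq_errors(r2, cfg$error_rate), NULL)
    ids <- sprintf("%s:%06d:%s", sample_id, seq_len(n), truth$site_id[si])
    names(r1) <- ids; names(r2) <- ids
    structure(list(ids = ids, r1 = r1, r2 = r2,
                   qual1 = setNames(rep(strrep(cfg$qual_char, nchar(r1[1])), n), ids),
                   qual2 = setNames(rep(strrep(cfg$qual_char, cfg$read_len), n), ids),
                   truth_site = setNames(truth$site_id[si], ids),
                   sample_id = sample_id, condition = condition),
              class = "paseq_reads")
  })
}

#' Pool several samples' simulated reads into one multiplexed run
#'
#' Concatenates per-sample read streams and shuffles pair order
#' deterministically, emulating a multiplexed sequencing run that
#' [demultiplex()] must then split by barcode.
#'
#' @param runs List of `paseq_reads` objects.
#' @param seed Shuffle seed.
#' @return A list with `ids`, `r1`, `r2`, `qual1`, `qual2`, `truth_site`.
#' @export
pool_reads <- function(runs, seed = 1L) {
  r1 <- unlist(lapply(runs, `[[`, "r1"))
  r2 <- unlist(lapply(runs, `[[`, "r2"))
  q1 <- unlist(lapply(runs, `[[`, "qual1"))
  q2 <- unlist(lapply(runs, `[[`, "qual2"))
  ts <- unlist(lapply(runs, `[[`, "truth_site"))
  ids <- unlist(lapply(runs, `[[`, "ids"))
  ord <- with_seed(seed, sample(length(ids)))
  list(ids = ids[ord], r1 = r1[ord], r2 = r2[ord],
       qual1 = q1[ord], qual2 = q2[ord], truth_site = ts[ord])
}
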