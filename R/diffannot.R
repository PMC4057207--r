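# diffannot: KD-vs-control differential adenylation and feature queries

#' Modal poly(A) site per gene near the annotated 3' end
#'
#' Candidate sites are retained sites on the gene's strand within
#' `window` bases of the annotated 3' end (+/- by default).  The modal
#' position is the candidate with the highest pooled raw count across
#' samples (ties broken towards the position closest to the annotated end,
#' then the most 5' in transcript orientation).  A gene is reported for a
#' sample when the modal position has at least `min_modal` raw reads in that
#' sample; rows carry per-sample raw and RPM values at the modal position.
#'
#' @param tbl Site table.
#' @param genes Gene annotation (data.frame with `contig`, `strand`,
#'   `gene_id`, `end3`).
#' @param window Half-width of the search window around the annotated end.
#' @param min_modal Minimum focal raw count at the modal position.
#' @param one_sided If `TRUE`, search only downstream of the annotated end
#'   (`end3 .. end3 + window` in transcript orientation).
#' @return data.table: `gene_id`, `contig`, `strand`, `modal_pos`, then
#'   `raw_<sample>`, `rpm_<sample>`, and a logical `pass_<sample>` column
#'   (modal raw >= `min_modal` in that sample).
#' @export
refseq_modal_sites <- function(tbl, genes, window = 50L, min_modal = 5L,
                               one_sided = FALSE) {
  tbl <- data.table::as.data.table(tbl)
  samples <- sort(unique(tbl$sample_id))
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    if (is.na(gn$end3)) {
      warning("gene without annotated 3' end skipped: ", gn$gene_id)
      next
    }
    if (one_sided) {
      lo <- if (gn$strand == "+") gn$end3 else gn$end3 - window
      hi <- if (gn$strand == "+") gn$end3 + window else gn$end3
    } else {
      lo <- gn$end3 - window; hi <- gn$end3 + window
    }
    cand <- tbl[contig == gn$contig & strand == gn$strand &
                  pos >= lo & pos <= hi & !templated_a & !below_min_reads]
    if (!nrow(cand)) next
    pooled <- cand[, .(raw = sum(raw)), by = pos]
    mx <- max(pooled$raw)
    best <- pooled$pos[pooled$raw == mx]
    if (length(best) > 1L) {
      d <- abs(best - gn$end3)
      best <- best[d == min(d)]
      best <- if (gn$strand == "+") min(best) else max(best)
    }
    row <- data.table::data.table(gene_id = gn$gene_id, contig = gn$contig,
                                  strand = gn$strand, modal_pos = best)
    for (s in samples) {
      at <- tbl[contig == gn$contig & strand == gn$strand & pos == best &
                  sample_id == s]
      row[[paste0("raw_", s)]] <- if (nrow(at)) at$raw else 0L
      row[[paste0("rpm_", s)]] <- if (nrow(at)) at$rpm else 0
      row[[paste0("pass_", s)]] <- (if (nrow(at)) at$raw else 0L) >= min_modal
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(data.table::data.table())
  data.table::rbindlist(out)
}

#' Coefficient of determination between two samples' modal-site signals
#'
#' Squared Pearson correlation of `log10` expression across genes with
#' positive signal in both samples (or `log10(x + pseudocount)` across all
#' shared genes when a positive pseudocount is supplied).  R^2 is reported
#' together with the correlation's sign, since anti-correlated data also
#' yield high R^2.
#'
#' @param a,b Numeric vectors of per-gene signal (e.g. modal-site RPM),
#'   matched by position.
#' @param pseudocount Added before the log; default 0 (zero-signal genes are
#'   excluded and counted separately).
#' @return List: `r2`, `slope_sign`, `n_used`, `n_excluded`.
#' @export
scatter_r2 <- function(a, b, pseudocount = 0) {
  stopifnot(length(a) == length(b))
  if (pseudocount > 0) {
    keep <- !is.na(a) & !is.na(b)
    x <- log10(a[keep] + pseudocount); y <- log10(b[keep] + pseudocount)
  } else {
    keep <- !is.na(a) & !is.na(b) & a > 0 & b > 0
    x <- log10(a[keep]); y <- log10(b[keep])
  }
  if (sum(keep) < 3L) stop_config("fewer than 3 shared genes")
  r <- stats::cor(x, y)
  list(r2 = r^2, slope_sign = sign(r), n_used = sum(keep),
       n_excluded = sum(!keep))
}

#' Bin log2 knockdown/control ratios into the standard histogram
#'
#' The centre bin labelled `0` covers log2 ratios in (-0.2, +0.2]; all other
#' bins are 0.4 wide and labelled by the outer boundary of the bin relative
#' to zero (+0.6, +1.0, ... and symmetrically negative).  Undefined ratios
#' (control zero, or missing) are excluded from binning and counted
#' separately.  The fraction of genes within a two-fold difference
#' (|log2| < 1) is reported.
#'
#' @param log2_ratios Numeric vector (may contain NA/Inf for undefined).
#' @return List: `histogram` (data.table `bin_label`, `outer_edge`, `n`),
#'   `frac_within_twofold`, `n_defined`, `n_undefined`.
#' @export
log2_histogram <- function(log2_ratios) {
  x <- log2_ratios
  undef <- is.na(x) | is.infinite(x)
  x <- x[!undef]
  outer_edge <- ifelse(abs(x) <= 0.2, 0,
                       sign(x) * (0.2 + 0.4 * ceiling((abs(x) - 0.2) / 0.4)))
  lab <- ifelse(outer_edge == 0, "0", sprintf("%+.1f", outer_edge))
  edges <- sort(unique(outer_edge))
  hist <- data.table::data.table(
    bin_label = ifelse(edges == 0, "0", sprintf("%+.1f", edges)),
    outer_edge = edges,
    n = as.integer(table(factor(outer_edge, levels = edges))[as.character(edges)]))
  list(histogram = hist,
       frac_within_twofold = if (length(x)) mean(abs(x) < 1) else NA_real_,
       n_defined = length(x), n_undefined = sum(undef))
}

#' Categorize peaks against gene ends and repeat intervals
#'
#' Precedence: `refseq_pa` if the peak mode lies within `window` bases of an
#' annotated 3' end on the matching strand; otherwise `repeat` if the mode
#' overlaps a repeat interval; otherwise `neither`.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param genes Gene annotation with `end3`.
#' @param repeats Repeat intervals.
#' @param window Gene-end window; default 50.
#' @return The peak table with a `category` column appended.
#' @export
categorize_peaks <- function(peaks, genes, repeats, window = 50L) {
  peaks <- data.table::as.data.table(peaks)
  cat <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i]
    near_gene <- any(genes$contig == p$contig & genes$strand == p$strand &
                       abs(genes$end3 - p$mode_pos) <= window)
    if (near_gene) {
      cat[i] <- "refseq_pa"
    } else if (!is.null(repeats) && nrow(repeats) &&
               any(repeats$contig == p$contig &
                     repeats$start <= p$mode_pos &
                     repeats$end >= p$mode_pos)) {
      cat[i] <- "repeat"
    } else {
      cat[i] <- "neither"
    }
  }
  peaks[, category := cat]
  peaks[]
}

#' Rank "neither"-category peaks by knockdown/control ratio
#'
#' Ratios are computed from mode-anchored window sums of raw reads
#' (`window_<sample>` columns).  Peaks with zero control reads get an
#' undefined ratio reported as `"N.D."` (not detected in control) and are
#' ranked above all finite ratios by default, or excluded via
#' `exclude_nd = TRUE`.
#'
#' @param peaks Categorized peak table ([categorize_peaks()]).
#' @param kd,ctrl Sample ids of the knockdown and control runs.
#' @param exclude_nd Drop control-zero peaks instead of ranking them first.
#' @return data.table sorted by descending ratio: `cluster_id`, `contig`,
#'   `strand`, `mode_pos` (1-based coordinate), `kd_reads`, `ctrl_reads`,
#'   `ratio`, `ratio_label`, `log2_ratio`, `category`.
#' @export
rank_neither <- function(peaks, kd, ctrl, exclude_nd = FALSE) {
  peaks <- data.table::as.data.table(peaks)
  sub <- peaks[category == "neither"]
  kdw <- sub[[paste0("window_", kd)]]
  ctw <- sub[[paste0("window_", ctrl)]]
  out <- data.table::data.table(
    cluster_id = sub$cluster_id, contig = sub$contig, strand = sub$strand,
    mode_pos = sub$mode_pos, kd_reads = kdw, ctrl_reads = ctw,
    ratio = ifelse(ctw > 0, kdw / ctw, NA_real_))
  out[, ratio_label := ifelse(is.na(ratio), "N.D.",
                              formatC(ratio, format = "fg", digits = 3))]
  out[, log2_ratio := log2(ratio)]
  if (exclude_nd) out <- out[!is.na(ratio)]
  # N.D. (control-zero) peaks first, by knockdown reads, then finite ratios
  nd <- out[is.na(ratio)][order(-kd_reads)]
  fin <- out[!is.na(ratio)][order(-ratio, -kd_reads)]
  data.table::rbindlist(list(nd, fin))
}

#' Directed scan for adenylated miRNA 5' leaders at Drosha cleavage sites
#'
#' For every annotated pre-miRNA hairpin, the predicted Drosha cleavage site
#' is the base immediately 5' of the hairpin in transcript orientation (the
#' position where the released 5' leader's adenylated 3' terminus falls).
#' Raw reads are summed over `drosha_site +/- tol` on the transcript strand,
#' deliberately bypassing the minimum-read flag (a directed query can report
#' sub-threshold counts); templated-A-flagged rows stay excluded.  Calls
#' with zero reads in both conditions are suppressed unless `all = TRUE`.
#'
#' @param tbl Site table.
#' @param hairpins Hairpin annotation (data.frame `contig`, `start`, `end`,
#'   `strand`, `mirna`, `cluster_id`).
#' @param genome Named character vector (used only to detect hairpins at
#'   contig edges, which are skipped with a warning).
#' @param kd,ctrl Sample ids.
#' @param tol Window half-width around the Drosha site; default 2.
#' @param all Keep zero-read hairpins.
#' @return data.table: `mirna`, `cluster_id`, `contig`, `strand`,
#'   `drosha_site`, `modal_pos` (position of the maximum knockdown count in
#'   the window; NA if no reads), `kd_reads`, `ctrl_reads`, `ratio`,
#'   `ratio_label` (`"N.D."` when control is zero).
#' @export
mirna_leader_scan <- function(tbl, hairpins, genome, kd, ctrl, tol = 2L,
                              all = FALSE) {
  tbl <- data.table::as.data.table(tbl)
  out <- list()
  for (i in seq_len(nrow(hairpins))) {
    hp <- hairpins[i, ]
    drosha <- if (hp$strand == "+") hp$start - 1L else hp$end + 1L
    L <- nchar(genome[[hp$contig]])
    if (drosha - tol < 1L || drosha + tol > L) {
      warning("hairpin at contig edge skipped: ", hp$mirna)
      next
    }
    kdr <- window_raw(tbl, hp$contig, hp$strand, drosha, tol, kd)
    ctr <- window_raw(tbl, hp$contig, hp$strand, drosha, tol, ctrl)
    if (!all && kdr == 0L && ctr == 0L) next
    win <- tbl[contig == hp$contig & strand == hp$strand &
                 pos >= drosha - tol & pos <= drosha + tol &
                 sample_id == kd & !templated_a]
    modal <- if (nrow(win)) {
      cand <- win$pos[win$raw == max(win$raw)]
      if (hp$strand == "+") min(cand) else max(cand)
    } else NA_integer_
    out[[length(out) + 1L]] <- data.table::data.table(
      mirna = hp$mirna, cluster_id = hp$cluster_id, contig = hp$contig,
      strand = hp$strand, drosha_site = drosha, modal_pos = modal,
      kd_reads = kdr, ctrl_reads = ctr,
      ratio = if (ctr > 0) kdr / ctr else NA_real_,
      ratio_label = if (ctr > 0) formatC(kdr / ctr, format = "fg", digits = 3)
                    else "N.D.")
  }
  if (!length(out))
    return(data.table::data.table(
      mirna = character(0), cluster_id = character(0), contig = character(0),
      strand = character(0), drosha_site = integer(0), modal_pos = integer(0),
      kd_reads = integer(0), ctrl_reads = integer(0), ratio = numeric(0),
      ratio_label = character(0)))
  data.table::rbindlist(out)
}

#' Positional adenylation profile around a feature's 3' end
#'
#' Offsets are relative to the annotated 3' end in transcript orientation:
#' offset 0 is the annotated terminal base, negative offsets lie inside the
#' feature (over-trimmed species), positive offsets beyond it.  Counts are
#' pooled over all copies sharing a copy group (identical tandem copies
#' whose multimapping reads were assigned at random).
#'
#' @param tbl Site table.
#' @param features data.frame with `contig`, `start`, `end`, `strand` and a
#'   `copy_group` column (feature id used if absent).
#' @param offset_range Integer vector `c(min_offset, max_offset)`.
#' @return data.table: `copy_group`, `offset`, `sample_id`, `raw`, `rpm`.
#' @export
positional_profile <- function(tbl, features, offset_range = c(-10L, 5L)) {
  tbl <- data.table::as.data.table(tbl)
  if (!"copy_group" %in% names(features))
    features$copy_group <- features[[ncol(features)]]
  out <- list()
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    end3 <- if (ft$strand == "+") ft$end else ft$start
    sub <- tbl[contig == ft$contig & strand == ft$strand & !templated_a]
    off <- if (ft$strand == "+") sub$pos - end3 else end3 - sub$pos
    keep <- off >= offset_range[1] & off <= offset_range[2]
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      copy_group = ft$copy_group, offset = off[keep],
      sample_id = sub$sample_id[keep], raw = sub$raw[keep],
      rpm = sub$rpm[keep])
  }
  if (!length(out))
    return(data.table::data.table(copy_group = character(0),
                                  offset = integer(0), sample_id = character(0),
                                  raw = integer(0), rpm = numeric(0)))
  data.table::rbindlist(out)[, .(raw = sum(raw), rpm = sum(rpm)),
                             by = .(copy_group, offset, sample_id)][
                               order(copy_group, offset, sample_id)]
}

#' Cumulative knockdown/control fold over an offset sub-range
#'
#' @param profile Output of [positional_profile()].
#' @param offsets Integer offsets to sum over (e.g. `-3:-1` for the
#'   over-trimmed species).
#' @param kd,ctrl Sample ids.
#' @param group Copy group; default the profile's first.
#' @return List: `kd_reads`, `ctrl_reads`, `fold` (NA when control is 0).
#' @export
profile_window_fold <- function(profile, offsets, kd, ctrl, group = NULL) {
  if (is.null(group)) group <- profile$copy_group[1]
  sub <- profile[copy_group == group & offset %in% offsets]
  kdr <- sum(sub[sample_id == kd]$raw)
  ctr <- sum(sub[sample_id == ctrl]$raw)
  list(kd_reads = kdr, ctrl_reads = ctr,
       fold = if (ctr > 0) kdr / ctr else NA_real_)
}

#' Fraction of 5' mates mapping fully inside a feature
#'
#' A quality check distinguishing bona fide processing products of a short
#' feature (all fragment 5' ends internal) from read-through transcription
#' (5' mates upstream of the feature).
#'
#' @param hits Mapped hit table (with `m5_start`, `m5_end`).
#' @param contig,start,end,strand Feature interval (1-based closed) and
#'   transcript strand.
#' @param pa_slack Hits whose adenylation position falls within
#'   `[start - pa_slack, end + pa_slack]` are attributed to the feature.
#' @return List: `fraction` (NA if no hits), `n_hits`, `n_inside`.
#' @export
five_prime_mate_qc <- function(hits, contig, start, end, strand,
                               pa_slack = 10L) {
  h <- data.table::as.data.table(hits)
  ctg <- contig; st <- strand
  sel <- h[h$contig == ctg & h$strand == st &
             pa_pos >= start - pa_slack & pa_pos <= end + pa_slack]
  if (!nrow(sel)) return(list(fraction = NA_real_, n_hits = 0L, n_inside = 0L))
  inside <- sel$m5_start >= start & sel$m5_end <= end
  list(fraction = mean(inside), n_hits = nrow(sel), n_inside = sum(inside))
}
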