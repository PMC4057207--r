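# peaks: Gaussian-kernel density clustering of adenylation sites

#' Default density threshold for cluster calling
#'
#' The density a lone `min_reads`-read site contributes at a distance of two
#' bandwidths from itself; isolated sites at the minimum read count always
#' clear it at their own position.
#'
#' @param min_reads Minimum read count used by the site filter.
#' @return Numeric threshold.
#' @export
default_density_threshold <- function(min_reads = 5L) min_reads * exp(-2)

#' Gaussian kernel density profile of adenylation read counts
#'
#' `density(x) = sum_s count(s) * exp(-((x - pos(s)) / bandwidth)^2 / 2)`,
#' computed per (contig, strand) over the retained sites of one sample.
#' The profile is evaluated (and implicitly non-zero) only within four
#' bandwidths of any site.
#'
#' @param tbl Site table (after [apply_min_reads()] and
#'   [filter_templated_a()]).
#' @param sample Focal sample id.
#' @param bandwidth Kernel bandwidth in bases; default 5, reflecting the
#'   near-single-nucleotide precision of PA-seq 3' ends.
#' @return data.table (`contig`, `strand`, `pos`, `density`).
#' @export
density_profile <- function(tbl, sample, bandwidth = 5) {
  if (bandwidth <= 0) stop_config("bandwidth must be positive")
  sites <- retained_sites(data.table::as.data.table(tbl), sample)
  out <- list()
  span <- ceiling(4 * bandwidth)
  for (grp in split(seq_len(nrow(sites)),
                    paste(sites$contig, sites$strand))) {
    pos <- sites$pos[grp]; cnt <- sites$raw[grp]
    grid <- sort(unique(as.vector(outer(pos, (-span):span, `+`))))
    d <- as.vector(exp(-(outer(grid, pos, `-`) / bandwidth)^2 / 2) %*% cnt)
    out[[length(out) + 1L]] <- data.table::data.table(
      contig = sites$contig[grp[1]], strand = sites$strand[grp[1]],
      pos = grid, density = d)
  }
  if (!length(out))
    return(data.table::data.table(contig = character(0), strand = character(0),
                                  pos = integer(0), density = numeric(0)))
  data.table::rbindlist(out)
}

#' Call clusters as maximal contiguous above-threshold density regions
#'
#' Regions are maximal runs of consecutive positions whose density is at
#' least `threshold`; clusters on different strands never merge, and every
#' retained site belongs to at most one cluster.
#'
#' @param dens Density profile from [density_profile()].
#' @param tbl Site table (to attach member sites).
#' @param sample Focal sample id.
#' @param threshold Density threshold; must be positive.
#' @return List with `clusters` (data.table `cluster_id`, `contig`,
#'   `strand`, `start`, `end`) and `members` (data.table `cluster_id`,
#'   `contig`, `strand`, `pos`, `raw`).
#' @export
call_clusters <- function(dens, tbl, sample,
                          threshold = default_density_threshold()) {
  if (threshold <= 0) stop_config("density threshold must be positive")
  sites <- retained_sites(data.table::as.data.table(tbl), sample)
  clusters <- list(); members <- list()
  cid <- 0L
  for (grp in split(seq_len(nrow(dens)), paste(dens$contig, dens$strand))) {
    sub <- dens[grp][density >= threshold]
    if (!nrow(sub)) next
    sub <- sub[order(pos)]
    run_id <- cumsum(c(1L, diff(sub$pos) > 1L))
    for (r in split(sub$pos, run_id)) {
      lo <- min(r); hi <- max(r)
      mem <- sites[contig == sub$contig[1] & strand == sub$strand[1] &
                     pos >= lo & pos <= hi]
      if (!nrow(mem)) next
      cid <- cid + 1L
      id <- sprintf("peak%04d", cid)
      clusters[[cid]] <- data.table::data.table(
        cluster_id = id, contig = sub$contig[1], strand = sub$strand[1],
        start = lo, end = hi)
      members[[cid]] <- data.table::data.table(
        cluster_id = id, contig = mem$contig, strand = mem$strand,
        pos = mem$pos, raw = mem$raw)
    }
  }
  list(clusters = if (length(clusters)) data.table::rbindlist(clusters) else
         data.table::data.table(cluster_id = character(0), contig = character(0),
                                strand = character(0), start = integer(0),
                                end = integer(0)),
       members = if (length(members)) data.table::rbindlist(members) else
         data.table::data.table(cluster_id = character(0), contig = character(0),
                                strand = character(0), pos = integer(0),
                                raw = integer(0)))
}

# type-1 (inverse-ECDF) quantile of a weighted position multiset
weighted_quantile_type1 <- function(pos, counts, p) {
  o <- order(pos)
  pos <- pos[o]; counts <- counts[o]
  n <- sum(counts)
  idx <- pmax(1, ceiling(p * n))
  cs <- cumsum(counts)
  pos[vapply(idx, function(i) which(cs >= i)[1], integer(1))]
}

#' Per-cluster peak statistics
#'
#' For each cluster: the mode (member position with the highest raw count in
#' the focal sample; ties broken towards the most 5' position in transcript
#' orientation), the empirical 95% interval of the read-position multiset
#' (2.5% and 97.5% inverse-ECDF quantiles, each read contributing its
#' position once), its width in bases, the narrow flag (width < 10), totals
#' per sample, and windowed sums of raw reads over mode +/- `window` for
#' every sample (computed from the full site table as a directed query, so
#' control-side counts below the minimum-read threshold still contribute).
#'
#' @param clusters Output of [call_clusters()].
#' @param tbl Site table.
#' @param focal_sample Sample whose counts define mode and interval.
#' @param window Half-width of the mode-anchored window; default 2 (a
#'   5-position window).
#' @return data.table, one row per cluster: `cluster_id`, `contig`,
#'   `strand`, `start`, `end`, `mode_pos`, `int95_lo`, `int95_hi`,
#'   `width95`, `narrow`, `total_focal`, then `total_<sample>` and
#'   `window_<sample>` columns.
#' @export
cluster_stats <- function(clusters, tbl, focal_sample, window = 2L) {
  tbl <- data.table::as.data.table(tbl)
  samples <- sort(unique(tbl$sample_id))
  out <- list()
  for (i in seq_len(nrow(clusters$clusters))) {
    cl <- clusters$clusters[i]
    mem <- clusters$members[cluster_id == cl$cluster_id]
    if (!nrow(mem)) stop_config("empty cluster: ", cl$cluster_id)
    # focal-sample counts at member positions (members were retained sites
    # of the focal sample, so counts are present)
    focal <- tbl[contig == cl$contig & strand == cl$strand &
                   sample_id == focal_sample & pos %in% mem$pos]
    mx <- max(focal$raw)
    cand <- focal$pos[focal$raw == mx]
    mode_pos <- if (cl$strand == "+") min(cand) else max(cand)
    q <- weighted_quantile_type1(focal$pos, focal$raw, c(0.025, 0.975))
    width95 <- abs(q[2] - q[1]) + 1L
    row <- data.table::data.table(
      cluster_id = cl$cluster_id, contig = cl$contig, strand = cl$strand,
      start = cl$start, end = cl$end, mode_pos = mode_pos,
      int95_lo = q[1], int95_hi = q[2], width95 = width95,
      narrow = width95 < 10,
      total_focal = sum(focal$raw))
    for (s in samples) {
      tot <- tbl[contig == cl$contig & strand == cl$strand &
                   sample_id == s & pos %in% mem$pos & !templated_a]
      row[[paste0("total_", s)]] <- sum(tot$raw)
      row[[paste0("window_", s)]] <-
        window_raw(tbl, cl$contig, cl$strand, mode_pos, window, s)
    }
    out[[i]] <- row
  }
  if (!length(out)) return(data.table::data.table())
  data.table::rbindlist(out)
}

#' Call peaks: density profile, clustering and statistics in one step
#'
#' @inheritParams density_profile
#' @inheritParams cluster_stats
#' @param threshold Density threshold; `NULL` uses
#'   [default_density_threshold()].
#' @return The [cluster_stats()] table.
#' @export
call_peaks <- function(tbl, sample, bandwidth = 5, threshold = NULL,
                       window = 2L) {
  if (is.null(threshold)) threshold <- default_density_threshold()
  dens <- density_profile(tbl, sample, bandwidth)
  cl <- call_clusters(dens, tbl, sample, threshold)
  cluster_stats(cl, tbl, focal_sample = sample, window = window)
}
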