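# sites: strand-aware per-nucleotide adenylation tallies, filters, RPM

#' Tally mapped hits into a per-nucleotide adenylation site table
#'
#' @param hits Data.table of mapped hits carrying a `sample_id` column, or a
#'   named list of per-sample hit tables from [map_pairs()].
#' @return A data.table (long format) keyed by (`contig`, `strand`, `pos`,
#'   `sample_id`) with `raw` counts and filter columns initialised:
#'   `rpm` (NA until [normalize_rpm()]), `below_min_reads` (FALSE until
#'   [apply_min_reads()]), `templated_a` (FALSE until
#'   [filter_templated_a()]).  Sites with zero reads in a sample are not
#'   materialised; downstream queries treat absence as zero.
#' @export
tally_hits <- function(hits) {
  if (is.list(hits) && !data.table::is.data.table(hits)) {
    hits <- data.table::rbindlist(
      lapply(hits, function(h) h$hits %||% h), idcol = "sample_id")
  }
  hits <- data.table::as.data.table(hits)
  if (!nrow(hits)) {
    return(data.table::data.table(
      contig = character(0), strand = character(0), pos = integer(0),
      sample_id = character(0), raw = integer(0), rpm = numeric(0),
      below_min_reads = logical(0), templated_a = logical(0)))
  }
  tbl <- hits[, .(raw = .N), by = .(contig, strand, pos = pa_pos, sample_id)]
  tbl[, `:=`(rpm = NA_real_, below_min_reads = FALSE, templated_a = FALSE)]
  data.table::setkey(tbl, contig, strand, pos, sample_id)
  tbl[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag sites below the minimum read count
#'
#' A site survives for a sample if and only if it has at least `min_reads`
#' mapped reads in that sample; flagging is per sample, not pooled.
#' Directed feature queries (for example [mirna_leader_scan()]) deliberately
#' bypass this flag.
#'
#' @param tbl Site table from [tally_hits()].
#' @param min_reads Minimum reads; default 5.
#' @return The table with `below_min_reads` updated (by reference semantics
#'   of data.table; also returned).
#' @export
apply_min_reads <- function(tbl, min_reads = 5L) {
  if (min_reads < 1L) stop_config("min_reads must be >= 1")
  tbl <- data.table::as.data.table(tbl)
  tbl[, below_min_reads := raw < min_reads]
  tbl[]
}

#' Normalize raw counts to reads per million mapped reads
#'
#' @param tbl Site table.
#' @param mapped_totals Named numeric vector: sample id -> total mapped reads
#'   for that sequencing run.
#' @return Table with `rpm = raw * 1e6 / mapped_totals[sample]`.
#' @export
normalize_rpm <- function(tbl, mapped_totals) {
  tbl <- data.table::as.data.table(tbl)
  miss <- setdiff(unique(tbl$sample_id), names(mapped_totals))
  if (length(miss))
    stop_config("no mapped total for sample(s): ", paste(miss, collapse = ", "))
  if (any(mapped_totals[unique(tbl$sample_id)] <= 0))
    stop_config("mapped totals must be positive")
  tbl[, rpm := raw * 1e6 / mapped_totals[sample_id]]
  tbl[]
}

# max run length of `target` and total count of `target` in a window string
a_run_stats <- function(win, target) {
  n_t <- nchar(win) - nchar(gsub(target, "", win, fixed = TRUE))
  runs <- gregexpr(paste0(target, "+"), win)[[1]]
  max_run <- if (runs[1] == -1L) 0L else max(attr(runs, "match.length"))
  c(max_run = max_run, count = n_t)
}

#' Flag sites over templated genomic adenosine stretches (internal priming)
#'
#' For each site the 20 genomic bases immediately downstream in transcript
#' orientation are examined (plus strand: positions `pos+1..pos+20` read
#' directly; minus strand: `pos-1..pos-20`, complemented).  The site is
#' flagged when that stretch contains a run of at least `run_len` A's or at
#' least `window_hits` A's in total -- the signature of oligo-dT priming
#' onto genomically encoded adenosines rather than a true poly(A) tail.
#' Windows truncated at a contig end are evaluated on the available bases
#' with both thresholds scaled proportionally (rounded up).
#'
#' Flagged rows are excluded from all downstream peak and differential
#' computations.
#'
#' @param tbl Site table.
#' @param genome Named character vector of contig sequences.
#' @param run_len Continuous-run threshold (default 6).
#' @param window Downstream window width (default 20).
#' @param window_hits Total-count threshold within the window (default 15).
#' @return Table with `templated_a` updated.
#' @export
filter_templated_a <- function(tbl, genome, run_len = 6L, window = 20L,
                               window_hits = 15L) {
  tbl <- data.table::as.data.table(tbl)
  if (!nrow(tbl)) return(tbl[])
  sites <- unique(tbl[, .(contig, strand, pos)])
  flag <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig[i]
    L <- nchar(genome[[ctg]])
    p <- sites$pos[i]
    if (sites$strand[i] == "+") {
      from <- p + 1L; to <- min(p + window, L)
      target <- "A"
    } else {
      from <- max(1L, p - window); to <- p - 1L
      target <- "T"          # A on the transcript strand
    }
    avail <- to - from + 1L
    if (avail <= 0L) next
    win <- substr(genome[[ctg]], from, to)
    rl <- ceiling(run_len * avail / window)
    wh <- ceiling(window_hits * avail / window)
    st <- a_run_stats(win, target)
    flag[i] <- st["max_run"] >= rl || st["count"] >= wh
  }
  sites[, templated_a := flag]
  tbl[, templated_a := NULL]
  out <- merge(tbl, sites, by = c("contig", "strand", "pos"), all.x = TRUE)
  data.table::setkey(out, contig, strand, pos, sample_id)
  out[]
}

# retained = usable for peaks/differential in a given sample
retained_sites <- function(tbl, sample) {
  tbl[sample_id == sample & !templated_a & !below_min_reads & raw > 0]
}

# raw reads at (contig, strand, pos window) per sample, templated_a excluded,
# min-read flag bypassed (directed query)
window_raw <- function(tbl, contig_q, strand_q, center, tol, sample) {
  sub <- tbl[contig == contig_q & strand == strand_q &
               pos >= center - tol & pos <= center + tol &
               sample_id == sample & !templated_a]
  sum(sub$raw)
}
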