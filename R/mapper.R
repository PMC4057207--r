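# mapper: exact k-mer index + pigeonhole seed-and-extend, toy-genome scale

#' Build an exact k-mer position index over a genome
#'
#' Every plus-strand k-mer occurrence is recorded; reads are looked up in
#' both orientations at query time.  Positions are stored in a concatenated
#' coordinate space and decoded back to (contig, position) on lookup.
#'
#' @param genome Named character vector of contig sequences.
#' @param k Seed length.  With up to 2 mismatches allowed, full sensitivity
#'   is guaranteed for reads of length `>= 3 * k` (pigeonhole principle).
#' @return A list of class `kmer_index`.
#' @export
#' @examples
#' idx <- build_kmer_index(c(chr = "ACGTACGTACGTAAA"), k = 4)
build_kmer_index <- function(genome, k = 10L) {
  k <- as.integer(k)
  stopifnot(k >= 4L)
  lens <- nchar(genome)
  offset <- c(0L, cumsum(lens + k))[seq_along(genome)]
  names(offset) <- names(genome)
  all_kmers <- character(0); all_glob <- integer(0)
  for (ci in seq_along(genome)) {
    L <- lens[ci]
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    all_kmers <- c(all_kmers, substring(genome[ci], starts, starts + k - 1L))
    all_glob <- c(all_glob, starts + offset[ci])
  }
  env <- if (length(all_glob)) list2env(split(all_glob, all_kmers),
                                        hash = TRUE)
         else new.env(hash = TRUE, parent = emptyenv())
  structure(list(env = env, k = k, genome = genome, lens = lens,
                 offset = offset, contigs = names(genome)),
            class = "kmer_index")
}

# placements of `s` matching the plus-strand text with <= max_mm
# substitutions; returns NULL or list(pos, ci, mm) (1-based starts)
scan_one_orientation <- function(s, len, index, max_mm) {
  k <- index$k
  if (len < k) return(NULL)
  seeds <- unique(c(seq.int(1L, len - k + 1L, by = k), len - k + 1L))
  env <- index$env
  starts <- integer(0)
  for (o in seeds) {
    hit <- env[[substr(s, o, o + k - 1L)]]
    if (!is.null(hit)) starts <- c(starts, hit - o + 1L)
  }
  if (!length(starts)) return(NULL)
  starts <- unique(starts)
  if (length(index$lens) == 1L) {
    ci <- rep.int(1L, length(starts)); pos <- starts
  } else {
    ci <- findInterval(starts, c(index$offset, Inf))
    pos <- starts - index$offset[ci]
  }
  ok <- pos >= 1L & pos + len - 1L <= index$lens[ci]
  if (!any(ok)) return(NULL)
  pos <- pos[ok]; ci <- ci[ok]
  text <- substring(index$genome[ci], pos, pos + len - 1L)
  sraw <- charToRaw(s)
  mm <- vapply(text, function(t) sum(charToRaw(t) != sraw), integer(1),
               USE.NAMES = FALSE)
  ok2 <- mm <= max_mm
  if (!any(ok2)) return(NULL)
  o <- order(ci[ok2], pos[ok2])
  list(pos = pos[ok2][o], ci = ci[ok2][o], mm = mm[ok2][o])
}

# both-orientation scan; rc may be precomputed (batch reverse complement)
scan_both <- function(s, index, max_mm, rc = NULL) {
  if (is.null(rc)) rc <- revcomp(s)
  len <- nchar(s)
  list(fw = scan_one_orientation(s, len, index, max_mm),
       rv = scan_one_orientation(rc, len, index, max_mm),
       len = len)
}

#' Enumerate genomic placements of a read with up to `max_mm` mismatches
#'
#' Seed k-mers are tiled across the read (plus a final flush seed); each
#' exact seed hit proposes a placement, which is then verified base by base.
#' For reads of length `>= 3 * k` and `max_mm <= 2` this enumerates exactly
#' the same set as a brute-force scan of every genomic offset on both
#' strands.  Strand `"+"` means the read matches the plus-strand text
#' directly; `"-"` means its reverse complement does.
#'
#' @param seq Read sequence.
#' @param index A [build_kmer_index()] object.
#' @param max_mm Maximum substitutions (indels are not modelled).
#' @return data.frame with `contig`, `start`, `end`, `strand`, `mm`,
#'   ordered by (strand, contig, start).
#' @export
kmer_candidates <- function(seq, index, max_mm = 2L) {
  sc <- scan_both(seq, index, max_mm)
  fmt <- function(x, strand) {
    if (is.null(x)) return(NULL)
    data.frame(contig = index$contigs[x$ci], start = x$pos,
               end = x$pos + sc$len - 1L, strand = strand, mm = x$mm,
               stringsAsFactors = FALSE)
  }
  out <- rbind(fmt(sc$fw, "+"), fmt(sc$rv, "-"))
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mm = integer(0), stringsAsFactors = FALSE)
  out[order(out$strand, out$contig, out$start), , drop = FALSE]
}

#' Mapping parameters
#'
#' @param max_mm Maximum mismatches allowed on each mate (templated portion
#'   only; the tag is already trimmed).
#' @param max_span Maximum outer span of a properly oriented pair, bases.
#' @param max_candidates Reads matching more than this many candidate
#'   positions are discarded; reads with 2..`max_candidates` placements are
#'   assigned to one uniformly at random.
#' @return List of class `map_params`.
#' @export
map_params <- function(max_mm = 2L, max_span = 1000L, max_candidates = 9L) {
  structure(list(max_mm = as.integer(max_mm), max_span = as.integer(max_span),
                 max_candidates = as.integer(max_candidates)),
            class = "map_params")
}

# candidate 3'-read placements having a compatible 5'-mate placement
# (opposite strand, inward-facing, outer span <= max_span); returns NULL or
# parallel vectors incl. the closest compatible mate interval
pair_valid_fast <- function(sc3, sc5, max_span) {
  len3 <- sc3$len; len5 <- sc5$len
  take <- function(p3, p5, strand3) {
    # strand3 "+": 3' read on plus text, mate must be on minus text (p5 = rv)
    if (is.null(p3) || is.null(p5)) return(NULL)
    n <- length(p3$pos)
    keep <- logical(n); m5s <- integer(n); m5e <- integer(n)
    for (i in seq_len(n)) {
      js <- which(p5$ci == p3$ci[i])
      if (!length(js)) next
      if (strand3 == "+") {
        ps <- p3$pos[i]; pe <- ps + len3 - 1L
        ms <- p5$pos[js]; me <- ms + len5 - 1L
        span <- me - ps + 1L
        ok <- ps <= ms & pe <= me & span <= max_span
      } else {
        m3s <- p3$pos[i]; m3e <- m3s + len3 - 1L
        ps <- p5$pos[js]; pe <- ps + len5 - 1L
        span <- m3e - ps + 1L
        ok <- ps <= m3s & pe <= m3e & span <= max_span
      }
      if (any(ok)) {
        keep[i] <- TRUE
        j <- js[ok][which.min(span[ok])]
        m5s[i] <- p5$pos[j]; m5e[i] <- p5$pos[j] + len5 - 1L
      }
    }
    if (!any(keep)) return(NULL)
    list(ci = p3$ci[keep], start = p3$pos[keep],
         end = p3$pos[keep] + len3 - 1L,
         strand3 = rep(strand3, sum(keep)),
         m5_start = m5s[keep], m5_end = m5e[keep],
         m5_strand = rep(if (strand3 == "+") "-" else "+", sum(keep)))
  }
  a <- take(sc3$fw, sc5$rv, "+")
  b <- take(sc3$rv, sc5$fw, "-")
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

#' Map oriented read pairs and call per-read adenylation positions
#'
#' For each pair, candidate positions are all genomic placements of the
#' 3' read with at most `max_mm` mismatches that have a compatible 5'-mate
#' placement (opposite strand, inward orientation, outer span within
#' `max_span`).  Pairs with no candidate are unmapped; pairs with more than
#' `max_candidates` placements are discarded as multimapped; pairs with
#' 2..`max_candidates` placements are assigned to one position uniformly at
#' random with a seeded generator.  If the chosen 3'-read placement overlaps
#' a repeat interval the pair is discarded with reason `"repeat"`.  The
#' adenylation position (`pa_pos`) is the templated base adjacent to the
#' trimmed TTT tag, reported on the transcript strand: a 3' read aligning to
#' the minus strand comes from a plus-strand transcript ending at its
#' rightmost aligned base, and vice versa.
#'
#' @param oriented Data.frame from [orient_pairs()] (`id`, `seq3`, `seq5`).
#' @param index A [build_kmer_index()].
#' @param repeats Optional repeat intervals (data.frame `contig`, `start`,
#'   `end`, 1-based closed).
#' @param params A [map_params()].
#' @param seed Seed for the multimap assignment stream; the same seed and
#'   input yield identical assignments.
#' @return List with `hits` (data.table: `id`, `contig`, `strand`, `pa_pos`,
#'   `n_candidates`, `aln_start`, `aln_end`, `m5_start`, `m5_end`,
#'   `m5_strand`) and `rejected` (data.table: `id`, `reason` in
#'   `"unmapped"`, `"multimapped"`, `"repeat"`).
#' @export
map_pairs <- function(oriented, index, repeats = NULL, params = map_params(),
                      seed = 1L) {
  n <- nrow(oriented)
  empty_hits <- data.table::data.table(
    id = character(0), contig = character(0), strand = character(0),
    pa_pos = integer(0), n_candidates = integer(0), aln_start = integer(0),
    aln_end = integer(0), m5_start = integer(0), m5_end = integer(0),
    m5_strand = character(0))
  empty_rej <- data.table::data.table(id = character(0), reason = character(0))
  if (!n) return(list(hits = empty_hits, rejected = empty_rej))

  # deduplicated candidate scans; reverse complements computed in one batch
  u3 <- unique(oriented$seq3)
  u5 <- unique(oriented$seq5)
  rc3 <- revcomp(u3); rc5 <- revcomp(u5)
  sc3 <- vector("list", length(u3)); names(sc3) <- u3
  for (i in seq_along(u3))
    sc3[[i]] <- scan_both(u3[i], index, params$max_mm, rc = rc3[i])
  sc5 <- vector("list", length(u5)); names(sc5) <- u5
  for (i in seq_along(u5))
    sc5[[i]] <- scan_both(u5[i], index, params$max_mm, rc = rc5[i])

  key <- paste(oriented$seq3, oriented$seq5, sep = "\r")
  groups <- split(seq_len(n), factor(key, levels = unique(key)))

  acc_id <- list(); acc_ci <- list(); acc_str <- list(); acc_pa <- list()
  acc_nc <- list(); acc_as <- list(); acc_ae <- list()
  acc_ms <- list(); acc_me <- list(); acc_m5str <- list()
  rej_id <- list(); rej_reason <- list()
  ai <- 0L; ri <- 0L
  with_seed(seed, {
    for (rows in groups) {
      r1 <- rows[1]
      valid <- pair_valid_fast(sc3[[oriented$seq3[r1]]],
                               sc5[[oriented$seq5[r1]]], params$max_span)
      nv <- if (is.null(valid)) 0L else length(valid$start)
      if (nv == 0L || nv > params$max_candidates) {
        ri <- ri + 1L
        rej_id[[ri]] <- oriented$id[rows]
        rej_reason[[ri]] <- rep(if (nv == 0L) "unmapped" else "multimapped",
                                length(rows))
      } else {
        pick <- if (nv == 1L) rep.int(1L, length(rows))
                else sample.int(nv, length(rows), replace = TRUE)
        ai <- ai + 1L
        acc_id[[ai]] <- oriented$id[rows]
        acc_ci[[ai]] <- valid$ci[pick]
        acc_str[[ai]] <- ifelse(valid$strand3[pick] == "-", "+", "-")
        acc_pa[[ai]] <- ifelse(valid$strand3[pick] == "-",
                               valid$end[pick], valid$start[pick])
        acc_nc[[ai]] <- rep.int(nv, length(rows))
        acc_as[[ai]] <- valid$start[pick]
        acc_ae[[ai]] <- valid$end[pick]
        acc_ms[[ai]] <- valid$m5_start[pick]
        acc_me[[ai]] <- valid$m5_end[pick]
        acc_m5str[[ai]] <- valid$m5_strand[pick]
      }
    }
  })
  hits <- if (ai) data.table::data.table(
    id = unlist(acc_id), contig = index$contigs[unlist(acc_ci)],
    strand = unlist(acc_str), pa_pos = as.integer(unlist(acc_pa)),
    n_candidates = unlist(acc_nc), aln_start = unlist(acc_as),
    aln_end = unlist(acc_ae), m5_start = unlist(acc_ms),
    m5_end = unlist(acc_me), m5_strand = unlist(acc_m5str))
  else empty_hits
  rejected <- if (ri) data.table::data.table(
    id = unlist(rej_id), reason = unlist(rej_reason))
  else empty_rej

  # repeat masking on the chosen placement (after random assignment, so the
  # assignment stays uniform over copies)
  if (!is.null(repeats) && nrow(hits) && nrow(repeats)) {
    drop <- rep(FALSE, nrow(hits))
    for (ctg in unique(repeats$contig)) {
      hi <- which(hits$contig == ctg)
      if (!length(hi)) next
      ri2 <- repeats$contig == ctg
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(hits$aln_start[hi], hits$aln_end[hi]),
        IRanges::IRanges(repeats$start[ri2], repeats$end[ri2]))
      drop[hi[ov]] <- TRUE
    }
    if (any(drop)) {
      rejected <- data.table::rbindlist(list(
        rejected,
        data.table::data.table(id = hits$id[drop], reason = "repeat")))
      hits <- hits[!drop]
    }
  }
  list(hits = hits, rejected = rejected)
}

#' Percent-mapped bookkeeping
#'
#' @param raw,mapped Integer vectors of raw and mapped read counts.
#' @return Percent mapped, rounded to one decimal; 0 (with a warning) where
#'   `raw` is zero.
#' @export
#' @examples
#' percent_mapped(15135078, 10853534)
percent_mapped <- function(raw, mapped) {
  out <- ifelse(raw > 0, round(100 * mapped / raw, 1), 0)
  if (any(raw == 0)) warning("raw read count of zero; percent reported as 0")
  out
}

#' Per-sample mapping summary table
#'
#' Mirrors the standard sequencing-run bookkeeping: raw reads, mapped reads,
#' percent mapped (one decimal) and the number of distinct genomic positions
#' hit, counted over (contig, strand, position).
#'
#' @param raw_counts Named integer vector: sample id -> raw (demultiplexed)
#'   pair count.
#' @param hits Data.table of hits with a `sample_id` column (see
#'   [run_paseq_pipeline()]), or a list of per-sample hit tables.
#' @return data.frame with one row per sample.
#' @export
mapping_summary <- function(raw_counts, hits) {
  if (is.list(hits) && !data.table::is.data.table(hits))
    hits <- data.table::rbindlist(hits, idcol = "sample_id")
  hits <- data.table::as.data.table(hits)
  out <- lapply(names(raw_counts), function(s) {
    h <- hits[sample_id == s]
    data.frame(sample_id = s, raw_reads = unname(raw_counts[s]),
               mapped_reads = nrow(h),
               percent_mapped = percent_mapped(unname(raw_counts[s]), nrow(h)),
               genomic_positions = nrow(unique(h[, .(contig, strand, pa_pos)])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
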