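# readprep: exact-barcode demultiplexing and TTT-tag orientation

#' Demultiplex paired reads by exact 5-nt barcode
#'
#' A pair is assigned to a sample if and only if the first five bases of
#' read 1 equal that sample's barcode exactly; no mismatch rescue is
#' attempted.  The barcode is trimmed from assigned read-1 sequences before
#' any tag logic.
#'
#' @param r1,r2 Character vectors of read sequences (read 1 carries the
#'   barcode); names are used as read ids.
#' @param barcodes Named character vector, sample id -> 5-mer barcode.
#'   Duplicated barcodes are a configuration error.
#' @return A list with `samples` (named list of data.frames `id`, `seq1`
#'   (barcode-trimmed), `seq2`), `unassigned` (same columns, untrimmed), and
#'   `counts` (named integer vector including `"unassigned"`).
#' @export
#' @examples
#' demultiplex(c(x = "ACGTAGGGG"), c(x = "CCCCTTTT"), c(s1 = "ACGTA"))$counts
demultiplex <- function(r1, r2, barcodes) {
  if (any(nchar(barcodes) != 5L))
    stop_config("all barcodes must be exactly 5 nt")
  if (anyDuplicated(barcodes))
    stop_config("duplicate barcodes: samples are not distinguishable")
  if (length(r1) != length(r2))
    stop_config("r1 and r2 must have equal length")
  ids <- names(r1)
  if (is.null(ids)) ids <- as.character(seq_along(r1))
  bc <- substr(r1, 1L, 5L)
  hit <- match(bc, barcodes)
  samples <- vector("list", length(barcodes))
  names(samples) <- names(barcodes)
  for (i in seq_along(barcodes)) {
    sel <- which(hit == i)
    samples[[i]] <- data.frame(
      id = ids[sel],
      seq1 = substr(r1[sel], 6L, nchar(r1[sel])),
      seq2 = unname(r2[sel]), stringsAsFactors = FALSE)
  }
  sel <- which(is.na(hit))
  unassigned <- data.frame(id = ids[sel], seq1 = unname(r1[sel]),
                           seq2 = unname(r2[sel]), stringsAsFactors = FALSE)
  counts <- c(vapply(samples, nrow, integer(1)), unassigned = nrow(unassigned))
  list(samples = samples, unassigned = unassigned, counts = counts)
}

#' Orient read pairs by the TTT 3'-end tag
#'
#' The mate whose sequence begins with exactly `TTT` is designated the
#' 3'-end read and its leading three T's are trimmed; the chemistry leaves
#' exactly three tag thymidines, so no longer T-run is scanned (a fourth
#' leading T is templated sequence).  Pairs where both mates or neither mate
#' start with TTT are rejected with distinct reason codes, as are pairs whose
#' 3' read is too short to map after trimming.
#'
#' @param pairs Data.frame with columns `id`, `seq1`, `seq2` (as produced by
#'   [demultiplex()]).
#' @param min_len Minimum 3'-read length after tag trimming; shorter pairs
#'   are rejected with reason `"too_short"`.
#' @return A list with `oriented` (data.frame `id`, `seq3` (tag-trimmed
#'   3' read), `seq5`, `tag_mate` (1 or 2)) and `rejected` (data.frame `id`,
#'   `reason` in `"ambiguous_tag"`, `"no_tag"`, `"too_short"`).
#' @export
#' @examples
#' p <- data.frame(id = "a", seq1 = "TTTGACCGT", seq2 = "CCGATAAGG")
#' orient_pairs(p)$oriented
orient_pairs <- function(pairs, min_len = 8L) {
  t1 <- startsWith(pairs$seq1, "TTT")
  t2 <- startsWith(pairs$seq2, "TTT")
  tag1 <- t1 & !t2
  tag2 <- t2 & !t1
  seq3 <- ifelse(tag1, substr(pairs$seq1, 4L, nchar(pairs$seq1)),
                 ifelse(tag2, substr(pairs$seq2, 4L, nchar(pairs$seq2)), NA))
  seq5 <- ifelse(tag1, pairs$seq2, ifelse(tag2, pairs$seq1, NA))
  short <- !is.na(seq3) & nchar(seq3) < min_len
  ok <- (tag1 | tag2) & !short
  reason <- ifelse(t1 & t2, "ambiguous_tag",
                   ifelse(!t1 & !t2, "no_tag",
                          ifelse(short, "too_short", NA)))
  list(oriented = data.frame(id = pairs$id[ok], seq3 = seq3[ok],
                             seq5 = seq5[ok],
                             tag_mate = ifelse(tag1[ok], 1L, 2L),
                             stringsAsFactors = FALSE),
       rejected = data.frame(id = pairs$id[!ok], reason = reason[!ok],
                             stringsAsFactors = FALSE))
}
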