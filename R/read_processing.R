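# Paired-end merging, primer-anchored barcode extraction, and counting.

#' Merge one read pair by overlap consensus
#'
#' Reverse-complements read 2 and scans every relative offset against
#' read 1, including the short-insert regime where the insert is shorter
#' than the reads and both mates read through into adapter. Among offsets
#' with overlap at least `min_overlap` and mismatch fraction at most
#' `max_mismatch_frac`, the one with the most matching bases wins (ties:
#' fewer mismatches, then the smaller insert). If no offset qualifies the
#' status is `"too_many_mismatches"` when the best-matching offset still
#' aligns at least `min_overlap` bases, and `"no_overlap"` otherwise. The
#' consensus spans the inferred insert only — adapter read-through on
#' either side is clipped — and at each disagreeing overlap position takes
#' the higher-quality base, ties going to read 1.
#'
#' @param pair a `read_pair` (see [simulate_read_pair()]).
#' @param min_overlap smallest acceptable overlap, nt.
#' @param max_mismatch_frac largest acceptable fraction of mismatching
#'   bases within the overlap.
#' @return a `merge_result`: list with `status` (one of `"merged"`,
#'   `"no_overlap"`, `"too_many_mismatches"`), `consensus` and `qual`
#'   (NA unless merged), `overlap_len`, `n_mismatch`.
#' @examples
#' arch <- library_architecture()
#' tpl <- assemble_template(arch, arch$spike_barcode)
#' rp <- simulate_read_pair(tpl, read_len = 75, error_rate = 0)
#' merge_pair(rp)$consensus == tpl
#' @export
merge_pair <- function(pair, min_overlap = 10L, max_mismatch_frac = 0.25) {
  stopifnot(inherits(pair, "read_pair"))
  res <- merge_pairs_cpp(pair$r1_seq, pair$r2_seq,
                         phred_to_string(list(pair$r1_qual)),
                         phred_to_string(list(pair$r2_qual)),
                         as.integer(min_overlap), max_mismatch_frac)
  structure(list(status = res$status[1],
                 consensus = res$consensus[1],
                 qual = res$qual[1],
                 overlap_len = res$overlap_len[1],
                 n_mismatch = res$n_mismatch[1]),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("merge:", x$status, "( overlap", x$overlap_len, "nt,",
      x$n_mismatch, "mismatches )\n")
  if (identical(x$status, "merged")) cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Merge every pair of a read set
#'
#' Vectorised [merge_pair()] over a `read_set`; distinct pairs are merged
#' once and multiplicities carried along.
#'
#' @param reads a `read_set` (see [simulate_reads()], [read_fastq()]).
#' @inheritParams merge_pair
#' @return the `read_set` with added columns `status`, `consensus`,
#'   `qual`, `overlap_len`, `n_mismatch`.
#' @export
merge_pairs <- function(reads, min_overlap = 10L, max_mismatch_frac = 0.25) {
  stopifnot(inherits(reads, "read_set"))
  qs <- attr(reads, "qual")
  q1 <- if (is.null(reads$q1)) rep(qs, nrow(reads)) else reads$q1
  q2 <- if (is.null(reads$q2)) rep(qs, nrow(reads)) else reads$q2
  res <- merge_pairs_cpp(reads$r1, reads$r2, q1, q2,
                         as.integer(min_overlap), max_mismatch_frac)
  for (col in names(res)) reads[[col]] <- res[[col]]
  reads
}

#' Extract the encoding barcode from merged consensus sequences
#'
#' Anchors on the two primer sites: `primer5` is located as the leftmost
#' match with at most `max_primer_mismatch` substitutions (no indels),
#' then `primer3` as the leftmost such match downstream of it. The
#' enclosed region is returned iff it has exactly `arch$barcode_length`
#' bases; otherwise the read is rejected with a reason code
#' (`primer5_not_found`, `primer3_not_found`, `bad_barcode_length`). A
#' wrong-length region is never returned silently.
#'
#' @param consensus character vector of merged sequences (NA entries are
#'   rejected as `primer5_not_found`).
#' @param arch a [library_architecture()].
#' @param max_primer_mismatch substitutions tolerated in each primer.
#' @return data.frame with columns `barcode` (NA when rejected) and
#'   `reason` (NA when extracted).
#' @examples
#' arch <- library_architecture()
#' extract_barcode(assemble_template(arch, "AAAACCCCGGGG"), arch)
#' @export
extract_barcode <- function(consensus, arch, max_primer_mismatch = 1L) {
  stopifnot(inherits(arch, "library_architecture"), max_primer_mismatch >= 0)
  extract_barcodes_cpp(as.character(consensus), arch$primer5, arch$primer3,
                       arch$barcode_length, as.integer(max_primer_mismatch))
}

#' Process a read set into a barcode count table
#'
#' Runs the full readout: merge each pair ([merge_pairs()]), extract the
#' barcode from each consensus ([extract_barcode()]), and tabulate. Counts
#' are molecule-weighted (a collapsed row with multiplicity `n`
#' contributes `n`). The accounting identity always holds: pairs in =
#' merged + no_overlap + too_many_mismatches, and merged = extracted +
#' rejected.
#'
#' @inheritParams merge_pairs
#' @inheritParams extract_barcode
#' @return a list with
#'   \describe{
#'     \item{counts}{`count_table` of extracted barcodes}
#'     \item{accounting}{named numeric vector: `pairs_in`, `merged`,
#'       `no_overlap`, `too_many_mismatches`, `extracted`,
#'       `rejected_primer5_not_found`, `rejected_primer3_not_found`,
#'       `rejected_bad_barcode_length`}
#'     \item{rejects}{data.frame of rejected distinct pairs with reasons}
#'   }
#' @export
process_reads <- function(reads, arch, min_overlap = 10L,
                          max_mismatch_frac = 0.25,
                          max_primer_mismatch = 1L) {
  merged <- merge_pairs(reads, min_overlap, max_mismatch_frac)
  ext <- extract_barcode(merged$consensus, arch, max_primer_mismatch)
  # merge failures are accounted as merge failures, not extraction rejects
  ext$reason[merged$status != "merged"] <- NA_character_
  ext$barcode[merged$status != "merged"] <- NA_character_
  ok <- !is.na(ext$barcode)
  counts <- tabulate_barcodes(ext$barcode[ok], merged$n[ok])
  wsum <- function(sel) sum(merged$n[sel])
  acct <- c(
    pairs_in = sum(merged$n),
    merged = wsum(merged$status == "merged"),
    no_overlap = wsum(merged$status == "no_overlap"),
    too_many_mismatches = wsum(merged$status == "too_many_mismatches"),
    extracted = wsum(ok),
    rejected_primer5_not_found = wsum(!is.na(ext$reason) &
                                        ext$reason == "primer5_not_found"),
    rejected_primer3_not_found = wsum(!is.na(ext$reason) &
                                        ext$reason == "primer3_not_found"),
    rejected_bad_barcode_length = wsum(!is.na(ext$reason) &
                                         ext$reason == "bad_barcode_length"))
  rej <- !ok & merged$status == "merged"
  rejects <- data.frame(r1 = merged$r1[rej], r2 = merged$r2[rej],
                        n = merged$n[rej], reason = ext$reason[rej],
                        stringsAsFactors = FALSE)
  list(counts = counts, accounting = acct, rejects = rejects)
}

#' Collapse near-miss barcodes onto abundant neighbours (optional)
#'
#' Sequencing errors in the encoding region create low-count satellite
#' barcodes one substitution away from a true barcode. This optional
#' cleanup reassigns each barcode's counts to a unique Hamming-distance-1
#' neighbour whose count is at least `ratio` times larger; ties (two or
#' more such neighbours) leave the barcode uncollapsed. Off by default in
#' the pipeline: exact-match counting is the baseline readout.
#'
#' @param counts a `count_table`.
#' @param ratio minimum neighbour/count abundance ratio for collapsing.
#' @return a `count_table` with satellites merged into their parents.
#' @export
collapse_hamming1 <- function(counts, ratio = 10) {
  stopifnot(inherits(counts, "count_table"), ratio > 1)
  if (nrow(counts) < 2) return(counts)
  cnt <- setNames(counts$count, counts$barcode)
  dest <- counts$barcode
  for (i in seq_len(nrow(counts))) {
    b <- counts$barcode[i]
    nb <- hamming1_neighbours(b)
    nb <- nb[nb %in% names(cnt)]
    big <- nb[cnt[nb] >= ratio * cnt[[b]]]
    if (length(big) == 1) dest[i] <- big
  }
  tabulate_barcodes(dest, counts$count)
}

hamming1_neighbours <- function(barcode) {
  ch <- strsplit(barcode, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(DNA_BASES, ch[i])) {
      v <- ch; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
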