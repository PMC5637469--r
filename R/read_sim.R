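# Illumina-like paired-end read simulation.
#
# The sequenced construct is adapter5 + template + adapter3. Read 1 starts
# at the template's first base and reads into adapter3 when read_len
# exceeds the insert ("adapter read-through", the normal situation for a
# 48 nt insert at 2x75 nt); read 2 reads the reverse complement from the
# other end and runs through into adapter5 likewise. Substitution errors
# are i.i.d. per base; indels are not modelled (substitution-dominant
# Illumina error profile). Qualities are constant Phred Q by default.

#' Default sequencing adapter pair
#'
#' Illumina adapter stubs flanking the insert: `adapter5` precedes the
#' template on the sense strand and appears (reverse-complemented) in
#' read 2 read-through; `adapter3` follows the template and appears in
#' read 1 read-through. The experiment's actual adapter sequences are not
#' public; these defaults are conventional TruSeq-style stubs and are
#' fully configurable.
#'
#' @return named character vector with elements `adapter5`, `adapter3`.
#' @export
default_adapters <- function() {
  c(adapter5 = "AATGATACGGCGACCACCGAGATCTACACTCTT",
    adapter3 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA")
}

# Error-free mate sequences for a set of templates at a given read length.
# Reads running past the end of the available adapter are padded with 'A'.
mate_prototypes <- function(templates, read_len, adapters) {
  pad <- strrep("A", read_len)
  fwd <- paste0(templates, adapters[["adapter3"]], pad)
  rev <- paste0(revcomp(templates), revcomp(adapters[["adapter5"]]), pad)
  list(r1 = substr(fwd, 1L, read_len), r2 = substr(rev, 1L, read_len))
}

#' Simulate one paired-end read from a template
#'
#' @param template the insert sequence (A/C/G/T), e.g. from
#'   [assemble_template()].
#' @param read_len read length in nt for both mates.
#' @param error_rate per-base substitution probability in `[0, 0.25]`.
#' @param adapters named character vector with `adapter5` and `adapter3`
#'   (see [default_adapters()]).
#' @param seed integer seed.
#' @param quality constant Phred quality assigned to every base, in
#'   `[2, 41]`.
#' @param origin_barcode optional truth tag recorded on the pair.
#' @return a `read_pair`: list with `r1_seq`, `r2_seq`, `r1_qual`,
#'   `r2_qual` (integer Phred vectors) and `origin_barcode`.
#' @examples
#' arch <- library_architecture()
#' tpl <- assemble_template(arch, arch$spike_barcode)
#' rp <- simulate_read_pair(tpl, read_len = 75, error_rate = 0, seed = 1)
#' substr(rp$r1_seq, 1, 48) == tpl
#' @export
simulate_read_pair <- function(template, read_len = 75L, error_rate = 0.001,
                               adapters = default_adapters(), seed = NULL,
                               quality = 30L, origin_barcode = NULL) {
  stopifnot(is_dna(template), nchar(template) > 0, read_len > 0,
            error_rate >= 0, error_rate <= 0.25,
            quality >= 2, quality <= 41)
  proto <- mate_prototypes(template, read_len, adapters)
  seqs <- c(proto$r1, proto$r2)
  if (error_rate > 0) {
    seqs <- with_seed(seed, {
      hit <- which(runif(2L * read_len) < error_rate)
      if (length(hit) > 0) {
        inject_errors_cpp(seqs,
                          which = ifelse(hit > read_len, 2L, 1L),
                          pos = as.integer((hit - 1L) %% read_len + 1L),
                          shift = sample(3L, length(hit), replace = TRUE))
      } else seqs
    })
  }
  structure(list(r1_seq = seqs[1], r2_seq = seqs[2],
                 r1_qual = rep(as.integer(quality), read_len),
                 r2_qual = rep(as.integer(quality), read_len),
                 origin_barcode = origin_barcode),
            class = "read_pair")
}

#' @export
print.read_pair <- function(x, ...) {
  cat("read pair (", nchar(x$r1_seq), "nt +", nchar(x$r2_seq), "nt )\n")
  cat("  r1:", x$r1_seq, "\n  r2:", x$r2_seq, "\n")
  if (!is.null(x$origin_barcode))
    cat("  origin barcode:", x$origin_barcode, "\n")
  invisible(x)
}

#' Simulate paired-end reads for a whole count table
#'
#' Generates `count` read pairs per barcode (one pair per sampled
#' molecule). Pairs are returned collapsed: identical pairs share a row
#' with a multiplicity column `n`, which keeps depth-`1e6` simulations in
#' desk-scale memory; [write_fastq()] expands to one FASTQ record per
#' molecule. The substitution-error model is exact i.i.d. per base: the
#' total error count is binomial over all sequenced bases and error
#' positions are uniform without replacement.
#'
#' @param counts a `count_table` of molecules to sequence.
#' @param arch a [library_architecture()].
#' @inheritParams simulate_read_pair
#' @return a `read_set`: data.frame with columns `r1`, `r2`, `origin`,
#'   `n`, plus attributes `read_len` and `qual` (the constant Phred+33
#'   quality string).
#' @export
simulate_reads <- function(counts, arch, read_len = 75L, error_rate = 0.001,
                           adapters = default_adapters(), seed = NULL,
                           quality = 30L) {
  stopifnot(inherits(counts, "count_table"),
            inherits(arch, "library_architecture"),
            read_len > 0, error_rate >= 0, error_rate <= 0.25)
  keep <- counts$count > 0
  bars <- counts$barcode[keep]
  mult <- counts$count[keep]
  proto <- mate_prototypes(assemble_template(arch, bars), read_len, adapters)
  N <- sum(mult)
  qs <- phred_to_string(list(rep(as.integer(quality), read_len)))
  empty <- function() {
    structure(data.frame(r1 = character(0), r2 = character(0),
                         origin = character(0), n = numeric(0),
                         stringsAsFactors = FALSE),
              class = c("read_set", "data.frame"),
              read_len = as.integer(read_len), qual = qs)
  }
  if (N == 0) return(empty())

  err <- with_seed(seed, {
    cells_per_mate <- N * read_len
    lapply(1:2, function(mate) {
      n_err <- rbinom(1L, cells_per_mate, error_rate)
      cell <- sample(cells_per_mate, n_err)
      list(read = (cell - 1) %/% read_len + 1,
           pos = as.integer((cell - 1) %% read_len + 1),
           shift = sample(3L, n_err, replace = TRUE))
    })
  })

  bounds <- c(0, cumsum(mult))
  err_reads <- sort(unique(c(err[[1]]$read, err[[2]]$read)))
  row_of <- findInterval(err_reads - 0.5, bounds)  # barcode row per read

  seqs <- list(proto$r1[row_of], proto$r2[row_of])
  for (mate in 1:2) {
    e <- err[[mate]]
    if (length(e$read) > 0) {
      seqs[[mate]] <- inject_errors_cpp(
        seqs[[mate]],
        which = match(e$read, err_reads),
        pos = e$pos, shift = e$shift)
    }
  }

  # multiplicities of untouched (error-free) pairs per barcode
  n_err_by_row <- tabulate(row_of, nbins = length(bars))
  n_clean <- mult - n_err_by_row
  ck <- n_clean > 0
  out <- data.frame(
    r1 = c(proto$r1[ck], seqs[[1]]),
    r2 = c(proto$r2[ck], seqs[[2]]),
    origin = c(bars[ck], bars[row_of]),
    n = c(n_clean[ck], rep(1, length(err_reads))),
    stringsAsFactors = FALSE)
  structure(out, class = c("read_set", "data.frame"),
            read_len = as.integer(read_len), qual = qs)
}

#' @export
print.read_set <- function(x, ...) {
  cat("read set:", format(sum(x$n), big.mark = ",", scientific = FALSE), "pairs (",
      nrow(x), "distinct ) at read length", attr(x, "read_len"), "nt\n")
  invisible(x)
}

#' Write or read paired FASTQ files
#'
#' `write_fastq` expands a `read_set` to one record per molecule (Phred+33)
#' in two synchronised files; `read_fastq` reads a pair of FASTQ files back
#' into a `read_set` with per-record multiplicity 1. Qualities are
#' preserved; reading a file with heterogeneous per-base qualities is
#' supported even though the simulator writes constant-quality reads.
#'
#' @param reads a `read_set` (see [simulate_reads()]).
#' @param path_r1,path_r2 FASTQ paths for mates 1 and 2.
#' @param prefix read-name prefix.
#' @return `write_fastq` returns the two paths invisibly; `read_fastq`
#'   returns a `read_set` with an extra `q1`/`q2` column when qualities
#'   vary between records.
#' @export
write_fastq <- function(reads, path_r1, path_r2, prefix = "read") {
  stopifnot(inherits(reads, "read_set"))
  idx <- rep(seq_len(nrow(reads)), times = reads$n)
  ids <- sprintf("%s_%07d", prefix, seq_along(idx))
  qs <- attr(reads, "qual")
  q1 <- if (is.null(reads$q1)) rep(qs, length(idx)) else reads$q1[idx]
  q2 <- if (is.null(reads$q2)) rep(qs, length(idx)) else reads$q2[idx]
  for (mate in 1:2) {
    dna <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(if (mate == 1) reads$r1[idx] else
                                 reads$r2[idx]),
      Biostrings::PhredQuality(if (mate == 1) q1 else q2))
    names(dna) <- ids
    # Biostrings warns that the qualities travel outside mcols; harmless
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(
        dna, if (mate == 1) path_r1 else path_r2),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  invisible(c(path_r1, path_r2))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path_r1, path_r2) {
  rd <- function(p) {
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
  }
  m1 <- rd(path_r1); m2 <- rd(path_r2)
  if (length(m1$seq) != length(m2$seq))
    stop("mate files have different numbers of records")
  out <- data.frame(r1 = unname(m1$seq), r2 = unname(m2$seq),
                    origin = NA_character_, n = rep(1, length(m1$seq)),
                    q1 = unname(m1$qual), q2 = unname(m2$qual),
                    stringsAsFactors = FALSE)
  structure(out, class = c("read_set", "data.frame"),
            read_len = if (nrow(out)) nchar(out$r1[1]) else NA_integer_,
            qual = if (nrow(out)) out$q1[1] else NA_character_)
}
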