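# Pre-selection library tables: barcode -> (class, frequency).

new_library_table <- function(barcode, class, frequency) {
  df <- data.frame(barcode = as.character(barcode),
                   class = as.character(class),
                   frequency = as.numeric(frequency),
                   stringsAsFactors = FALSE)
  structure(df, class = c("library_table", "data.frame"))
}

validate_library_table <- function(lib, arch = NULL) {
  stopifnot(is.data.frame(lib),
            all(c("barcode", "class", "frequency") %in% names(lib)))
  if (anyDuplicated(lib$barcode))
    stop("library table contains duplicate barcodes")
  if (!all(lib$class %in% c("catalyst", "inactive")))
    stop("library classes must be 'catalyst' or 'inactive'")
  if (any(lib$frequency < 0))
    stop("library frequencies must be non-negative")
  if (nrow(lib) > 0 && abs(sum(lib$frequency) - 1) > 1e-12)
    stop("library frequencies must sum to 1 (got ",
         format(sum(lib$frequency), digits = 15), ")")
  if (!is.null(arch) && nrow(lib) > 0 &&
      any(nchar(lib$barcode) != arch$barcode_length))
    stop("all barcodes must have length ", arch$barcode_length)
  invisible(lib)
}

#' @export
print.library_table <- function(x, ...) {
  cat("DEL library table:", nrow(x), "members (",
      sum(x$class == "catalyst"), "catalyst,",
      sum(x$class == "inactive"), "inactive )\n")
  spike <- x[x$class == "catalyst", , drop = FALSE]
  if (nrow(spike) > 0)
    cat("  spike-in frequency:",
        paste(signif(spike$frequency, 6), collapse = ", "), "\n")
  print(head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# 0-based integer index -> barcode string, lexicographic in A<C<G<T.
int_to_barcode <- function(i, length) {
  if (length == 0L) return(rep("", length(i)))
  digits <- matrix(0L, nrow = length(i), ncol = length)
  x <- i
  for (pos in length:1) {
    digits[, pos] <- x %% 4
    x <- x %/% 4
  }
  m <- matrix(DNA_BASES[digits + 1L], nrow = length(i))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

barcode_to_int <- function(b) {
  chars <- strsplit(b, "", fixed = TRUE)
  vapply(chars, function(ch) {
    sum((match(ch, DNA_BASES) - 1) * 4^(rev(seq_along(ch)) - 1))
  }, numeric(1))
}

#' Generate a synthetic background library of distinct barcodes
#'
#' Draws `n_background` distinct barcodes uniformly from the
#' `4^barcode_length` encoding space, excluding the spike-in barcode, and
#' assigns each class `"inactive"` with uniform frequency. This emulates
#' the inactive pool into which the positive control is diluted; the
#' spike-in itself is added afterwards with [spike_in()].
#'
#' For `barcode_length <= 15` the sample is drawn directly from the
#' enumerated index space (exactly uniform without replacement); longer
#' barcodes use rejection sampling of random strings.
#'
#' @param arch a [library_architecture()].
#' @param n_background number of distinct inactive barcodes,
#'   `0 <= n_background <= 4^barcode_length - 1`.
#' @param seed integer seed; the same seed always yields the same table.
#' @return a `library_table` (data.frame with columns barcode, class,
#'   frequency).
#' @examples
#' arch <- library_architecture(barcode_length = 2, spike_barcode = "GA",
#'                              digest_site = "GA", digest_site_offset = 0)
#' generate_library(arch, n_background = 15, seed = 1)  # full 2-mer space
#' @export
generate_library <- function(arch, n_background, seed = NULL) {
  stopifnot(inherits(arch, "library_architecture"))
  n_background <- as.numeric(n_background)
  space <- barcode_space_size(arch$barcode_length)
  if (n_background < 0 || n_background > space - 1)
    stop("n_background must be between 0 and 4^barcode_length - 1 = ",
         space - 1)
  if (n_background == 0)
    return(new_library_table(character(0), character(0), numeric(0)))
  barcodes <- with_seed(seed, {
    if (arch$barcode_length <= 15L) {
      spike_idx <- barcode_to_int(arch$spike_barcode)
      idx <- sample.int(space - 1L, n_background) - 1L
      # shift indices at/after the spike's so it is never drawn
      idx <- ifelse(idx >= spike_idx, idx + 1L, idx)
      int_to_barcode(idx, arch$barcode_length)
    } else {
      out <- character(0)
      while (length(out) < n_background) {
        cand <- random_barcodes(2 * (n_background - length(out)),
                                arch$barcode_length)
        cand <- setdiff(unique(cand), c(out, arch$spike_barcode))
        out <- c(out, cand)
      }
      out[seq_len(n_background)]
    }
  })
  new_library_table(barcodes, "inactive", rep(1 / n_background, n_background))
}

#' Dilute the positive-control spike-in into a background library
#'
#' Adds the architecture's spike barcode with class `"catalyst"` at
#' frequency `1 / dilution` (the mock selections use 500-fold and
#' 2000-fold dilutions) and rescales the background frequencies by
#' `1 - 1/dilution` so the table still sums to 1.
#'
#' @param library a background `library_table` (no catalyst rows).
#' @param arch a [library_architecture()].
#' @param dilution dilution factor, `>= 1`; the spike-in pre-selection
#'   frequency is `f0 = 1/dilution`.
#' @return a `library_table` including the spike-in.
#' @examples
#' arch <- library_architecture()
#' lib <- spike_in(generate_library(arch, 100, seed = 1), arch, 500)
#' lib$frequency[lib$class == "catalyst"]  # 0.002
#' @export
spike_in <- function(library, arch, dilution) {
  stopifnot(inherits(arch, "library_architecture"))
  validate_library_table(library, arch)
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution < 1)
    stop("dilution must be a single number >= 1")
  if (arch$spike_barcode %in% library$barcode)
    stop("spike barcode already present in the library")
  f0 <- 1 / dilution
  out <- new_library_table(
    c(arch$spike_barcode, library$barcode),
    c("catalyst", library$class),
    c(f0, library$frequency * (1 - f0)))
  validate_library_table(out, arch)
}

#' Aggregate two-class library for analytic work
#'
#' Collapses the whole inactive background into a single pooled pseudo-member
#' at frequency `1 - 1/dilution`. Because selection survival depends only on
#' the class, the spike-in's post-selection frequency distribution under
#' [simulate_selection()] is identical to that of a fully enumerated
#' background; the aggregate form is convenient for fast analytic checks.
#'
#' @inheritParams spike_in
#' @param background_barcode barcode label for the pooled background row.
#' @return a two-row `library_table`.
#' @export
aggregate_library <- function(arch, dilution,
                              background_barcode =
                                strrep("A", arch$barcode_length)) {
  stopifnot(inherits(arch, "library_architecture"))
  if (background_barcode == arch$spike_barcode)
    stop("background_barcode collides with the spike barcode")
  bg <- new_library_table(background_barcode, "inactive", 1)
  spike_in(bg, arch, dilution)
}

#' Read or write a library table as TSV
#'
#' Columns: `barcode`, `class`, `frequency` (tab-separated, with header).
#'
#' @param lib a `library_table`.
#' @param path file path.
#' @return `read_library` returns a `library_table`; `write_library`
#'   returns `path` invisibly.
#' @export
write_library <- function(lib, path) {
  validate_library_table(lib)
  write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "numeric"))
  validate_library_table(new_library_table(df$barcode, df$class, df$frequency))
}

#' Export library templates as FASTA
#'
#' Assembles the full `primer5 + barcode + primer3` template for every
#' library member and writes a FASTA file (one record per member, named by
#' barcode and class).
#'
#' @param lib a `library_table`.
#' @param arch a [library_architecture()].
#' @param path output FASTA path.
#' @export
write_templates_fasta <- function(lib, arch, path) {
  validate_library_table(lib, arch)
  seqs <- Biostrings::DNAStringSet(assemble_template(arch, lib$barcode))
  names(seqs) <- paste0(lib$barcode, " class=", lib$class)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
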