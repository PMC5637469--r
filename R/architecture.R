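#' Encoding-DNA architecture of a DEL selection template
#'
#' A selection template is `primer5 + barcode + primer3`: two fixed
#' primer-binding sites for amplification flanking a randomised encoding
#' region whose sequence identifies the attached small molecule. The
#' default architecture is the 48 nt layout used throughout this package:
#' two 18 nt primer sites and a 12 nt encoding region, which can encode
#' `4^12` (more than 16 million) distinct molecules. The positive-control
#' spike-in barcode carries an EcoRV recognition site (`GATATC`) so that
#' its enrichment can also be followed by an in-silico restriction digest.
#'
#' The primer and adapter sequences of the original experiment are not
#' public; the defaults are fixed GC-balanced 18-mers and are fully
#' overridable.
#'
#' @param primer5,primer3 fixed primer-site sequences (A/C/G/T).
#' @param barcode_length length of the randomised encoding region, nt.
#' @param spike_barcode barcode of the positive-control spike-in; must have
#'   length `barcode_length` and contain `digest_site` at
#'   `digest_site_offset`.
#' @param digest_site restriction-enzyme recognition sequence carried by
#'   the spike-in (default EcoRV, `GATATC`).
#' @param digest_site_offset 0-based offset of `digest_site` within
#'   `spike_barcode`.
#' @return an object of class `library_architecture`.
#' @examples
#' arch <- library_architecture()
#' nchar(assemble_template(arch, arch$spike_barcode))  # 48
#' @export
library_architecture <- function(primer5 = "ACGTGCTAGCATCGGACT",
                                 primer3 = "TGCACGATCGTAGCCTGA",
                                 barcode_length = 12L,
                                 spike_barcode = "CTAGATATCGAT",
                                 digest_site = "GATATC",
                                 digest_site_offset = 3L) {
  stopifnot(is_dna(primer5), is_dna(primer3), is_dna(spike_barcode),
            is_dna(digest_site))
  barcode_length <- as.integer(barcode_length)
  digest_site_offset <- as.integer(digest_site_offset)
  if (barcode_length < 0L)
    stop("barcode_length must be a non-negative integer")
  if (nchar(spike_barcode) != barcode_length)
    stop("spike_barcode must have length barcode_length (",
         barcode_length, " nt)")
  if (barcode_length > 0L) {
    found <- substr(spike_barcode, digest_site_offset + 1L,
                    digest_site_offset + nchar(digest_site))
    if (found != digest_site)
      stop("digest_site '", digest_site, "' not found in spike_barcode at ",
           "offset ", digest_site_offset)
  }
  structure(
    list(primer5 = primer5, primer3 = primer3,
         barcode_length = barcode_length,
         spike_barcode = spike_barcode,
         digest_site = digest_site,
         digest_site_offset = digest_site_offset),
    class = "library_architecture")
}

#' @export
print.library_architecture <- function(x, ...) {
  cat("DEL template architecture:",
      nchar(x$primer5), "+", x$barcode_length, "+", nchar(x$primer3),
      "nt =", template_length(x), "nt\n")
  cat("  primer5:      ", x$primer5, "\n")
  cat("  encoding:     ", strrep("N", x$barcode_length),
      " (", format(barcode_space_size(x$barcode_length), big.mark = ","),
      " barcodes)\n", sep = "")
  cat("  primer3:      ", x$primer3, "\n")
  cat("  spike barcode:", x$spike_barcode, "  digest site:", x$digest_site,
      "at offset", x$digest_site_offset, "\n")
  invisible(x)
}

#' Total template length implied by an architecture
#' @param arch a [library_architecture()].
#' @return integer, `nchar(primer5) + barcode_length + nchar(primer3)`.
#' @export
template_length <- function(arch) {
  nchar(arch$primer5) + arch$barcode_length + nchar(arch$primer3)
}

#' Number of distinct DNA barcodes of a given length
#'
#' An encoding region of `length` nt can take `4^length` sequences; at the
#' default 12 nt this exceeds 16 million, the diversity quoted for
#' split-and-pool DEL synthesis.
#'
#' @param length barcode length in nt (non-negative integer).
#' @return `4^length` as a double (exact for `length <= 26`).
#' @examples
#' barcode_space_size(12)  # 16777216
#' @export
barcode_space_size <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0 || length != floor(length))
    stop("length must be a single non-negative integer")
  4^length
}

#' Assemble a full template from an architecture and a barcode
#'
#' @param arch a [library_architecture()].
#' @param barcode character vector of barcodes, each of
#'   `arch$barcode_length` nt.
#' @return `primer5 + barcode + primer3` for each barcode.
#' @examples
#' arch <- library_architecture()
#' assemble_template(arch, "AAAACCCCGGGG")
#' @export
assemble_template <- function(arch, barcode) {
  stopifnot(inherits(arch, "library_architecture"))
  if (any(nchar(barcode) != arch$barcode_length))
    stop("all barcodes must have length ", arch$barcode_length)
  paste0(arch$primer5, barcode, arch$primer3)
}
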