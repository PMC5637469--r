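# Barcode count tables (barcode -> non-negative integer count).

#' Construct a barcode count table
#'
#' @param barcode character vector of distinct barcodes.
#' @param count non-negative integer counts, same length.
#' @return a `count_table`: data.frame with columns `barcode`, `count`.
#' @export
count_table <- function(barcode, count) {
  barcode <- as.character(barcode)
  count <- as.numeric(count)
  if (anyDuplicated(barcode))
    stop("count table barcodes must be distinct")
  if (any(count < 0) || any(count != floor(count)))
    stop("counts must be non-negative integers")
  structure(data.frame(barcode = barcode, count = count,
                       stringsAsFactors = FALSE),
            class = c("count_table", "data.frame"))
}

#' Total number of reads in a count table
#' @param x a `count_table`.
#' @return the sum of counts.
#' @export
total_count <- function(x) sum(x$count)

#' @export
print.count_table <- function(x, ...) {
  cat("Barcode count table:", nrow(x), "barcodes,",
      format(total_count(x), big.mark = ",", scientific = FALSE), "reads\n")
  print(head(as.data.frame(x[order(-x$count), ])))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read or write a count table as TSV
#'
#' Columns: `barcode`, `count` (tab-separated, with header).
#'
#' @param x a `count_table`.
#' @param path file path.
#' @return `read_counts` returns a `count_table`; `write_counts` returns
#'   `path` invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, colClasses = c("character", "numeric"))
  count_table(df$barcode, df$count)
}

# Tabulate a vector of observed barcodes (with optional per-observation
# multiplicities) into a count_table, dropping nothing.
tabulate_barcodes <- function(barcodes, weights = NULL) {
  if (length(barcodes) == 0) return(count_table(character(0), numeric(0)))
  if (is.null(weights)) weights <- rep(1, length(barcodes))
  agg <- rowsum(weights, group = barcodes)
  count_table(rownames(agg), as.vector(agg))
}
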