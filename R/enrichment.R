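# Per-barcode fold enrichment between pre- and post-selection count
# tables, and the in-silico restriction-digest readout.

#' Per-barcode fold enrichment between two count tables
#'
#' Fold enrichment of a barcode is the ratio of its post-selection to
#' pre-selection frequency. With pseudocount `alpha` and `K` barcodes in
#' the union of the two tables, smoothed frequencies are
#' `(count + alpha) / (total + alpha * K)`; `alpha = 0` gives exact
#' frequency ratios, the default `alpha = 0.5` (Haldane–Anscombe) keeps
#' barcodes absent from one table finite. The 95% confidence interval is
#' the normal approximation on the log ratio with variance
#' `1/a - 1/n1 + 1/b - 1/n2` on the smoothed counts. Barcodes absent
#' pre-selection are flagged (`present_pre = FALSE`), never dropped.
#'
#' @param pre,post `count_table`s for the starting and post-selection
#'   libraries; both totals must be positive.
#' @param pseudocount smoothing pseudocount `alpha >= 0`.
#' @param conf confidence level for the interval.
#' @return an `enrichment_table`: data.frame with one row per barcode in
#'   the union, columns `barcode`, `pre_count`, `post_count`, `pre_freq`,
#'   `post_freq`, `enrichment`, `ci_low`, `ci_high`, `present_pre`,
#'   `present_post`, sorted by descending enrichment.
#' @examples
#' pre <- count_table(c("AA", "AC"), c(500, 999500))
#' post <- count_table(c("AA", "AC"), c(600120, 399880))
#' fold_enrichment(pre, post, pseudocount = 0)
#' @export
fold_enrichment <- function(pre, post, pseudocount = 0.5, conf = 0.95) {
  stopifnot(inherits(pre, "count_table"), inherits(post, "count_table"),
            pseudocount >= 0, conf > 0, conf < 1)
  n1 <- total_count(pre); n2 <- total_count(post)
  if (n1 == 0 || n2 == 0)
    stop("both count tables must have positive totals")
  bars <- union(pre$barcode, post$barcode)
  K <- length(bars)
  a0 <- pre$count[match(bars, pre$barcode)]; a0[is.na(a0)] <- 0
  b0 <- post$count[match(bars, post$barcode)]; b0[is.na(b0)] <- 0
  a <- a0 + pseudocount
  b <- b0 + pseudocount
  N1 <- n1 + pseudocount * K
  N2 <- n2 + pseudocount * K
  pre_freq <- a / N1
  post_freq <- b / N2
  enr <- post_freq / pre_freq
  se <- sqrt(pmax(1 / a - 1 / N1 + 1 / b - 1 / N2, 0))
  z <- qnorm(1 - (1 - conf) / 2)
  out <- data.frame(barcode = bars, pre_count = a0, post_count = b0,
                    pre_freq = pre_freq, post_freq = post_freq,
                    enrichment = enr,
                    ci_low = enr * exp(-z * se),
                    ci_high = enr * exp(z * se),
                    present_pre = a0 > 0, present_post = b0 > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$enrichment, out$barcode), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            pseudocount = pseudocount, conf = conf,
            pre_total = n1, post_total = n2)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Enrichment table:", nrow(x), "barcodes (pre",
      format(attr(x, "pre_total"), big.mark = ",", scientific = FALSE), "reads, post",
      format(attr(x, "post_total"), big.mark = ",", scientific = FALSE),
      "reads, pseudocount", attr(x, "pseudocount"), ")\n")
  top <- head(as.data.frame(x))
  top$pre_freq <- signif(top$pre_freq, 4)
  top$post_freq <- signif(top$post_freq, 4)
  top$enrichment <- signif(top$enrichment, 5)
  top$ci_low <- signif(top$ci_low, 4); top$ci_high <- signif(top$ci_high, 4)
  print(top)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Fraction of molecules whose template carries the digest site
#'
#' Emulates the gel readout: an EcoRV digest cuts every molecule whose
#' (assembled, full-length) template contains the recognition site, so
#' the cut fraction on a gel tracks the spike-in's frequency. The whole
#' template is scanned, not just the encoding region, so a background
#' barcode that spuriously creates the site — including across a
#' primer/barcode junction — is counted too.
#'
#' @param table a `count_table`.
#' @param arch a [library_architecture()].
#' @return the fraction of molecules (counts) whose template contains
#'   `arch$digest_site`; 0 for an empty table.
#' @examples
#' arch <- library_architecture()
#' digest_fraction(count_table(arch$spike_barcode, 10), arch)  # 1
#' @export
digest_fraction <- function(table, arch) {
  stopifnot(inherits(table, "count_table"),
            inherits(arch, "library_architecture"))
  tot <- total_count(table)
  if (tot == 0) return(0)
  tpl <- assemble_template(arch, table$barcode)
  has <- grepl(arch$digest_site, tpl, fixed = TRUE)
  sum(table$count[has]) / tot
}

#' Summarise an enrichment analysis
#'
#' Builds the run summary: the spike-in's fold enrichment and rank, the
#' nominal-dilution alternative (post-frequency over `1/dilution` instead
#' of over the measured pre-frequency), and the pre/post digest fractions
#' (the in-silico gel). `write_report()` writes the full record table as
#' TSV and the summary (with metadata) as JSON; regenerating from the
#' same inputs is byte-identical.
#'
#' @param records an `enrichment_table` from [fold_enrichment()].
#' @param arch a [library_architecture()].
#' @param pre,post the `count_table`s the records were computed from
#'   (used for the digest fractions).
#' @param dilution optional nominal dilution factor; when given, the
#'   summary also reports post-frequency / (1/dilution).
#' @param metadata named list recorded verbatim in the summary (seeds,
#'   parameters).
#' @return an `enrichment_report`: list with `records` and `summary`.
#' @export
enrichment_report <- function(records, arch, pre, post, dilution = NULL,
                              metadata = list()) {
  stopifnot(inherits(records, "enrichment_table"), nrow(records) > 0,
            inherits(arch, "library_architecture"))
  spike_row <- match(arch$spike_barcode, records$barcode)
  spike <- if (is.na(spike_row)) NULL else records[spike_row, ]
  summary <- list(
    n_barcodes = nrow(records),
    pre_total = attr(records, "pre_total"),
    post_total = attr(records, "post_total"),
    pseudocount = attr(records, "pseudocount"),
    spike_barcode = arch$spike_barcode,
    spike_detected = !is.na(spike_row),
    spike_enrichment = if (!is.na(spike_row)) spike$enrichment else NA,
    spike_enrichment_ci = if (!is.na(spike_row))
      c(spike$ci_low, spike$ci_high) else NA,
    spike_rank = if (!is.na(spike_row))
      which(records$barcode[order(-records$enrichment)] ==
              arch$spike_barcode)[1] else NA,
    spike_pre_freq = if (!is.na(spike_row)) spike$pre_freq else NA,
    spike_post_freq = if (!is.na(spike_row)) spike$post_freq else NA,
    spike_enrichment_vs_nominal = if (!is.na(spike_row) &&
                                      !is.null(dilution))
      spike$post_freq * dilution else NA,
    digest_fraction_pre = digest_fraction(pre, arch),
    digest_fraction_post = digest_fraction(post, arch),
    metadata = metadata)
  structure(list(records = records, summary = summary),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  s <- x$summary
  cat("Mock-selection enrichment report\n")
  cat("  barcodes analysed:   ", s$n_barcodes, "\n")
  if (isTRUE(s$spike_detected)) {
    cat("  spike-in enrichment: ", signif(s$spike_enrichment, 6),
        "-fold (95% CI ", signif(s$spike_enrichment_ci[1], 5), "-",
        signif(s$spike_enrichment_ci[2], 5), "), rank ", s$spike_rank,
        "\n", sep = "")
    if (!is.na(s$spike_enrichment_vs_nominal))
      cat("  vs nominal dilution: ",
          signif(s$spike_enrichment_vs_nominal, 6), "-fold\n", sep = "")
  } else {
    cat("  spike-in not detected\n")
  }
  cat("  digest fraction:      pre ", signif(s$digest_fraction_pre, 4),
      " -> post ", signif(s$digest_fraction_post, 4),
      "  (in-silico gel)\n", sep = "")
  invisible(x)
}

#' @rdname enrichment_report
#' @param report an `enrichment_report`.
#' @param records_path output TSV path for the full record table.
#' @param summary_path output JSON path for the summary.
#' @export
write_report <- function(report, records_path, summary_path) {
  stopifnot(inherits(report, "enrichment_report"))
  df <- as.data.frame(report$records)
  frq <- c("pre_freq", "post_freq", "enrichment", "ci_low", "ci_high")
  df[frq] <- lapply(df[frq], formatC, digits = 10, format = "g")
  write.table(df, records_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(report$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(c(records_path, summary_path))
}
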