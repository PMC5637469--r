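# End-to-end mock selection: generate -> select -> sequence -> process ->
# enrich, from a single config with one master seed.

#' Default run configuration
#'
#' Nested list of defaults for [run_mock_selection()], mirroring the
#' sequencing mock selection: 48 nt architecture (18+12+18), `1e5`
#' distinct background barcodes, 2000-fold spike-in dilution, survival
#' probabilities `p_cat = 0.30` and `p_bg = 1e-4` (survival ratio 3000,
#' the calibration at which the expected spike enrichment is ~1200-fold),
#' depth `1e6` reads per sample, 2x75 nt reads at per-base error rate
#' 0.001, and exact frequency-ratio enrichment (pseudocount 0 for the
#' spike readout; see [fold_enrichment()] for smoothing).
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    architecture = list(
      primer5 = "ACGTGCTAGCATCGGACT",
      primer3 = "TGCACGATCGTAGCCTGA",
      barcode_length = 12L,
      spike_barcode = "CTAGATATCGAT",
      digest_site = "GATATC",
      digest_site_offset = 3L),
    library = list(n_background = 1e5, dilution = 2000),
    selection = list(p_cat = 0.30, p_bg = 1e-4,
                     depth_pre = 1e6, depth_post = 1e6,
                     pcr_bias_sd = 0),
    reads = list(read_len = 75L, error_rate = 0.001,
                 adapter5 = unname(default_adapters()[["adapter5"]]),
                 adapter3 = unname(default_adapters()[["adapter3"]]),
                 quality = 30L),
    analysis = list(pseudocount = 0, max_primer_mismatch = 1L,
                    min_overlap = 10L, max_mismatch_frac = 0.25),
    io = list(outdir = NULL, write_fastq = TRUE),
    seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Reads a (possibly partial) YAML config and fills unspecified fields
#' from [default_config()].
#'
#' @param path YAML file path.
#' @param overrides optional named list applied on top of the file
#'   (precedence: overrides > file > defaults).
#' @return a full configuration list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- merge_config(default_config(), yaml::read_yaml(path))
  merge_config(cfg, overrides)
}

config_architecture <- function(config) {
  a <- config$architecture
  library_architecture(a$primer5, a$primer3, a$barcode_length,
                       a$spike_barcode, a$digest_site,
                       a$digest_site_offset)
}

validate_config <- function(config) {
  arch <- config_architecture(config)  # validates the architecture block
  with(config$library, {
    stopifnot(n_background >= 0, dilution >= 1)
  })
  with(config$selection, {
    stopifnot(p_cat > 0, p_cat <= 1, p_bg >= 0, p_bg < 1,
              depth_pre >= 1, depth_post >= 1, pcr_bias_sd >= 0)
  })
  with(config$reads, {
    stopifnot(read_len > 0, error_rate >= 0, error_rate <= 0.25,
              quality >= 2, quality <= 41)
  })
  with(config$analysis, {
    stopifnot(pseudocount >= 0, max_primer_mismatch >= 0, min_overlap >= 1,
              max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  })
  invisible(arch)
}

#' Run one full mock selection in silico
#'
#' Executes the five pipeline stages in order — generate the background
#' library and dilute in the spike ([generate_library()], [spike_in()]),
#' simulate selection and sequencing depth ([simulate_selection()]),
#' simulate paired-end reads for both samples ([simulate_reads()]),
#' process reads back to barcode counts ([process_reads()]), and compute
#' per-barcode fold enrichment and the digest readout
#' ([fold_enrichment()], [enrichment_report()]). All randomness derives
#' from `config$seed`; a second run with the same config is identical.
#' When `config$io$outdir` is set, every intermediate artifact is written
#' there (library TSV, truth and observed count tables, FASTQ pairs,
#' enrichment TSV, summary JSON, resolved config YAML).
#'
#' @param config a configuration list (see [default_config()],
#'   [read_run_config()]); partial configs are completed from the
#'   defaults.
#' @return a `mock_selection` object: list with the resolved `config`,
#'   `arch`, `library`, `truth` (sequencing-free count tables), observed
#'   `pre`/`post` counts, `accounting` per sample, `enrichment` records
#'   and the `report`.
#' @examples
#' cfg <- list(library = list(n_background = 200, dilution = 500),
#'             selection = list(depth_pre = 2e4, depth_post = 2e4),
#'             seed = 7)
#' run <- run_mock_selection(cfg)
#' run$report$summary$spike_enrichment
#' @export
run_mock_selection <- function(config = list()) {
  config <- merge_config(default_config(), config)
  arch <- validate_config(config)
  seeds <- child_seeds(config$seed, 4L)
  adapters <- c(adapter5 = config$reads$adapter5,
                adapter3 = config$reads$adapter3)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("mock-selection stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  lib <- stage("library", {
    bg <- generate_library(arch, config$library$n_background,
                           seed = seeds[1])
    spike_in(bg, arch, config$library$dilution)
  })
  sim <- stage("selection", {
    params <- selection_params(config$selection$p_cat, config$selection$p_bg,
                               config$selection$depth_pre,
                               config$selection$depth_post,
                               pcr_bias_sd = config$selection$pcr_bias_sd,
                               seed = seeds[2])
    simulate_selection(lib, params)
  })
  reads <- stage("reads", {
    list(pre = simulate_reads(sim$pre, arch, config$reads$read_len,
                              config$reads$error_rate, adapters,
                              seed = seeds[3],
                              quality = config$reads$quality),
         post = simulate_reads(sim$post, arch, config$reads$read_len,
                               config$reads$error_rate, adapters,
                               seed = seeds[4],
                               quality = config$reads$quality))
  })
  proc <- stage("process", {
    lapply(reads, process_reads, arch = arch,
           min_overlap = config$analysis$min_overlap,
           max_mismatch_frac = config$analysis$max_mismatch_frac,
           max_primer_mismatch = config$analysis$max_primer_mismatch)
  })
  res <- stage("enrich", {
    records <- fold_enrichment(proc$pre$counts, proc$post$counts,
                               config$analysis$pseudocount)
    report <- enrichment_report(
      records, arch, proc$pre$counts, proc$post$counts,
      dilution = config$library$dilution,
      metadata = list(seed = config$seed, stage_seeds = seeds,
                      p_cat = config$selection$p_cat,
                      p_bg = config$selection$p_bg,
                      dilution = config$library$dilution,
                      depth_pre = config$selection$depth_pre,
                      depth_post = config$selection$depth_post,
                      read_len = config$reads$read_len,
                      error_rate = config$reads$error_rate,
                      pseudocount = config$analysis$pseudocount))
    list(records = records, report = report)
  })

  out <- structure(
    list(config = config, arch = arch, library = lib, truth = sim,
         pre = proc$pre$counts, post = proc$post$counts,
         accounting = list(pre = proc$pre$accounting,
                           post = proc$post$accounting),
         enrichment = res$records, report = res$report),
    class = "mock_selection")

  if (!is.null(config$io$outdir)) {
    dir <- config$io$outdir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      write_library(lib, file.path(dir, "library.tsv"))
      write_counts(sim$pre, file.path(dir, "truth_pre_counts.tsv"))
      write_counts(sim$post, file.path(dir, "truth_post_counts.tsv"))
      if (isTRUE(config$io$write_fastq)) {
        write_fastq(reads$pre, file.path(dir, "pre_R1.fastq"),
                    file.path(dir, "pre_R2.fastq"), prefix = "pre")
        write_fastq(reads$post, file.path(dir, "post_R1.fastq"),
                    file.path(dir, "post_R2.fastq"), prefix = "post")
      }
      write_counts(proc$pre$counts, file.path(dir, "observed_pre_counts.tsv"))
      write_counts(proc$post$counts,
                   file.path(dir, "observed_post_counts.tsv"))
      write_report(res$report, file.path(dir, "enrichment.tsv"),
                   file.path(dir, "summary.json"))
      yaml::write_yaml(config, file.path(dir, "config.yaml"))
    })
  }
  out
}

#' @export
print.mock_selection <- function(x, ...) {
  cat("Mock selection run (seed ", x$config$seed, ")\n", sep = "")
  cat("  library: ", nrow(x$library), " members, dilution 1/",
      x$config$library$dilution, "\n", sep = "")
  cat("  selection: p_cat = ", x$config$selection$p_cat, ", p_bg = ",
      x$config$selection$p_bg, "\n", sep = "")
  for (s in c("pre", "post")) {
    a <- x$accounting[[s]]
    cat("  ", s, " sample: ", format(a[["pairs_in"]], big.mark = ",", scientific = FALSE),
        " pairs, ", format(a[["merged"]], big.mark = ",", scientific = FALSE), " merged, ",
        format(a[["extracted"]], big.mark = ",", scientific = FALSE), " barcodes extracted\n",
        sep = "")
  }
  print(x$report)
  invisible(x)
}

#' @export
summary.mock_selection <- function(object, ...) {
  object$report$summary
}

#' Write deterministic miniature fixture datasets
#'
#' Builds small, fully deterministic datasets for tests and examples:
#' `"tiny"` is a complete 2-mer library (16 barcodes, the spike carrying
#' a 2 nt digest site) with 1000 read pairs; `"small"` is 1000 12 nt
#' barcodes with `1e4` read pairs under the default 48 nt architecture.
#' Repeated calls write identical bytes.
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir output directory.
#' @return the output directory, invisibly; files written: `config.yaml`,
#'   `library.tsv`, `*_R1.fastq`/`*_R2.fastq`, count tables, enrichment
#'   TSV and summary JSON (the full [run_mock_selection()] artifact set).
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    list(architecture = list(primer5 = "ACGTGC", primer3 = "TGCACG",
                             barcode_length = 2L, spike_barcode = "GA",
                             digest_site = "GA", digest_site_offset = 0L),
         library = list(n_background = 15, dilution = 16),
         selection = list(p_cat = 0.5, p_bg = 0.05,
                          depth_pre = 1000, depth_post = 1000),
         reads = list(read_len = 20L),
         seed = 20L)
  } else {
    list(library = list(n_background = 1000, dilution = 500),
         selection = list(depth_pre = 1e4, depth_post = 1e4,
                          p_cat = 0.2495, p_bg = 0.002),
         seed = 21L)
  }
  cfg$io <- list(outdir = dir, write_fastq = TRUE)
  run_mock_selection(cfg)
  invisible(dir)
}
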