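test_that("error-free reads copy the template and read through into adapter", {
  arch <- library_architecture()
  tpl <- assemble_template(arch, "GATTACAGATTA")
  ad <- default_adapters()

  rp <- simulate_read_pair(tpl, read_len = 40, error_rate = 0, seed = 1)
  expect_equal(rp$r1_seq, substr(tpl, 1, 40))
  expect_equal(rp$r2_seq, substr(revcomp(tpl), 1, 40))

  long <- simulate_read_pair(tpl, read_len = 75, error_rate = 0, seed = 1)
  expect_equal(substr(long$r1_seq, 1, 48), tpl)
  expect_equal(substr(long$r1_seq, 49, 75), substr(ad[["adapter3"]], 1, 27))
  expect_equal(substr(long$r2_seq, 1, 48), revcomp(tpl))
  expect_equal(substr(long$r2_seq, 49, 75),
               substr(revcomp(ad[["adapter5"]]), 1, 27))
  expect_true(all(long$r1_qual == 30L))
  expect_true(all(long$r2_qual == 30L))
})

test_that("substitution errors occur at the binomial rate", {
  arch <- library_architecture()
  counts <- count_table("GATTACAGATTA", 1000)
  reads <- simulate_reads(counts, arch, read_len = 50, error_rate = 0.01,
                          seed = 77)
  expect_equal(sum(reads$n), 1000)
  proto <- delselect:::mate_prototypes(
    assemble_template(arch, "GATTACAGATTA"), 50, default_adapters())
  n_err <- sum(reads$n * (mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$r1, proto$r1) + mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$r2, proto$r2)))
  expected <- 1000 * 100 * 0.01  # pairs x bases per pair x rate
  expect_lt(abs(n_err - expected), 3 * sqrt(expected * 0.99))
})

test_that("merging recovers the template and respects quality tie-breaks", {
  arch <- library_architecture()
  tpl <- assemble_template(arch, arch$spike_barcode)
  rp <- simulate_read_pair(tpl, read_len = 75, error_rate = 0, seed = 2)
  res <- merge_pair(rp)
  expect_equal(res$status, "merged")
  expect_equal(res$consensus, tpl)
  expect_equal(res$overlap_len, 48)

  # one disagreement: high-quality r1 base wins, then swap the qualities
  r1 <- tpl
  r2_err <- revcomp(tpl)
  substr(r2_err, 10, 10) <- "A"  # disagrees unless template has A there
  pos_in_r1 <- nchar(tpl) - 10 + 1
  stopifnot(substr(r1, pos_in_r1, pos_in_r1) != "T")
  q40 <- rep(40L, nchar(tpl)); q10 <- rep(10L, nchar(tpl))
  take1 <- merge_pair(make_read_pair(r1, r2_err, q40, q10))
  expect_equal(take1$status, "merged")
  expect_equal(take1$consensus, tpl)
  take2 <- merge_pair(make_read_pair(r1, r2_err, q10, q40))
  expect_equal(substr(take2$consensus, pos_in_r1, pos_in_r1), "T")
  # equal qualities: tie goes to r1
  tie <- merge_pair(make_read_pair(r1, r2_err, q40, q40))
  expect_equal(tie$consensus, tpl)

  # unrelated reads share nothing
  off <- merge_pair(make_read_pair(strrep("A", 30), strrep("A", 30)))
  expect_equal(off$status, "no_overlap")
})

test_that("merging matches the naive reference on random pairs", {
  arch <- tiny_arch()
  set.seed(42)
  for (i in 1:60) {
    bar <- delselect:::random_barcodes(1, 2)
    tpl <- assemble_template(arch, bar)
    rp <- simulate_read_pair(tpl, read_len = sample(10:20, 1),
                             error_rate = sample(c(0, 0.05, 0.2), 1),
                             seed = i)
    # random qualities exercise the consensus tie-breaks
    rp$r1_qual <- sample(2:41, length(rp$r1_qual), replace = TRUE)
    rp$r2_qual <- sample(2:41, length(rp$r2_qual), replace = TRUE)
    got <- merge_pair(rp, min_overlap = 5, max_mismatch_frac = 0.3)
    ref <- oracle_merge(rp$r1_seq, rp$r2_seq, rp$r1_qual, rp$r2_qual,
                        min_overlap = 5, max_mismatch_frac = 0.3)
    expect_equal(got$status, ref$status, info = paste("case", i))
    expect_equal(got$consensus, ref$consensus, info = paste("case", i))
  }
})

test_that("merging is strand-symmetric up to documented tie-breaks", {
  arch <- library_architecture()
  set.seed(7)
  for (i in 1:20) {
    tpl <- assemble_template(arch, delselect:::random_barcodes(1, 12))
    rp <- simulate_read_pair(tpl, read_len = 60, error_rate = 0.02,
                             seed = 1000 + i)
    fwd <- merge_pair(rp)
    swapped <- make_read_pair(rp$r2_seq, rp$r1_seq, rp$r2_qual, rp$r1_qual)
    rev <- merge_pair(swapped)
    expect_equal(rev$status, fwd$status)
    if (fwd$status == "merged") {
      expect_equal(nchar(rev$consensus), nchar(fwd$consensus))
      expect_equal(rev$overlap_len, fwd$overlap_len)
      # with no overlap disagreement there is no tie-break: consensi are
      # reverse complements of each other
      if (fwd$n_mismatch == 0)
        expect_equal(revcomp(rev$consensus), fwd$consensus)
    }
  }
})

test_that("barcode extraction is primer-anchored with mismatch tolerance", {
  arch <- library_architecture()
  tpl <- assemble_template(arch, "AAAACCCCGGGG")
  expect_equal(extract_barcode(tpl, arch)$barcode, "AAAACCCCGGGG")

  mut1 <- tpl
  substr(mut1, 3, 3) <- if (substr(tpl, 3, 3) == "A") "C" else "A"
  expect_equal(extract_barcode(mut1, arch, 1)$barcode, "AAAACCCCGGGG")

  mut2 <- mut1
  substr(mut2, 7, 7) <- if (substr(tpl, 7, 7) == "A") "C" else "A"
  got <- extract_barcode(mut2, arch, 1)
  expect_true(is.na(got$barcode))
  expect_equal(got$reason, "primer5_not_found")
  expect_equal(extract_barcode(mut2, arch, 2)$barcode, "AAAACCCCGGGG")

  # wrong-length insert is rejected, never mis-returned
  bad <- paste0(arch$primer5, "AAAACCCCGGG", arch$primer3)
  expect_equal(extract_barcode(bad, arch)$reason, "bad_barcode_length")
  no3 <- paste0(arch$primer5, "AAAACCCCGGGG", strrep("A", 18))
  expect_equal(extract_barcode(no3, arch)$reason, "primer3_not_found")
})

test_that("round trip recovers every barcode at zero error rate", {
  set.seed(11)
  for (i in 1:15) {
    blen <- sample(2:12, 1)
    spike <- delselect:::random_barcodes(1, blen)
    # primers 8-13 nt keep every template short enough that even 25 nt
    # reads overlap by >= the default min_overlap of 10
    arch <- library_architecture(
      primer5 = delselect:::random_barcodes(1, sample(8:13, 1)),
      primer3 = delselect:::random_barcodes(1, sample(8:13, 1)),
      barcode_length = blen, spike_barcode = spike,
      digest_site = spike, digest_site_offset = 0)
    bar <- delselect:::random_barcodes(1, blen)
    tpl <- assemble_template(arch, bar)
    for (read_len in c(25, 40, 75)) {
      rp <- simulate_read_pair(tpl, read_len = read_len, error_rate = 0,
                               seed = i)
      res <- merge_pair(rp)
      expect_equal(res$status, "merged")
      expect_equal(extract_barcode(res$consensus, arch, 0)$barcode, bar,
                   info = paste("len", read_len, "case", i))
    }
  }
})

test_that("read processing accounts for every pair and is bit-exact at zero error", {
  arch <- library_architecture()
  lib <- spike_in(generate_library(arch, 200, seed = 6), arch, 500)
  sim <- simulate_selection(lib, selection_params(0.2495, 0.002, 2e4, 2e4,
                                                  seed = 6))
  reads <- simulate_reads(sim$post, arch, read_len = 75, error_rate = 0,
                          seed = 6)
  proc <- process_reads(reads, arch, max_primer_mismatch = 0)
  a <- proc$accounting
  expect_equal(a[["pairs_in"]], 2e4)
  expect_equal(a[["pairs_in"]],
               a[["merged"]] + a[["no_overlap"]] + a[["too_many_mismatches"]])
  expect_equal(a[["merged"]],
               a[["extracted"]] + sum(a[grep("^rejected", names(a))]))
  # observed counts identical to the simulated truth
  truth <- sim$post[sim$post$count > 0, ]
  got <- proc$counts[match(truth$barcode, proc$counts$barcode), ]
  expect_equal(got$count, truth$count)
  expect_equal(total_count(proc$counts), total_count(sim$post))

  # with errors the identity still holds, counts need not match truth
  noisy <- simulate_reads(sim$post, arch, read_len = 75, error_rate = 0.01,
                          seed = 6)
  pn <- process_reads(noisy, arch)
  an <- pn$accounting
  expect_equal(an[["pairs_in"]],
               an[["merged"]] + an[["no_overlap"]] +
                 an[["too_many_mismatches"]])
  expect_equal(an[["merged"]],
               an[["extracted"]] + sum(an[grep("^rejected", names(an))]))
})

test_that("hamming-1 collapse folds satellites, leaves ties alone", {
  parent <- "AAAACCCCGGGG"
  sat <- parent; substr(sat, 1, 1) <- "C"
  tbl <- count_table(c(parent, sat), c(1000, 5))
  col <- collapse_hamming1(tbl)
  expect_equal(col$count[col$barcode == parent], 1005)
  # two equally abundant parents: ambiguous, keep uncollapsed
  p2 <- parent; substr(p2, 12, 12) <- "A"
  sat2 <- parent; substr(sat2, 12, 12) <- "C"
  tbl2 <- count_table(c(parent, p2, sat2), c(1000, 1000, 5))
  col2 <- collapse_hamming1(tbl2)
  expect_equal(sort(col2$barcode), sort(tbl2$barcode))
})

test_that("FASTQ export and import round-trip a read set", {
  arch <- tiny_arch()
  lib <- spike_in(generate_library(arch, 10, seed = 1), arch, 16)
  sim <- simulate_selection(lib, selection_params(0.5, 0.05, 500, 500,
                                                  seed = 2))
  reads <- simulate_reads(sim$pre, arch, read_len = 12, error_rate = 0.01,
                          seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1, f2)
  back <- read_fastq(f1, f2)
  expect_equal(sum(back$n), sum(reads$n))
  expand <- function(x, col) sort(rep(x[[col]], times = x$n))
  expect_equal(expand(back, "r1"), expand(reads, "r1"))
  expect_equal(expand(back, "r2"), expand(reads, "r2"))
  expect_true(all(back$q1 == attr(reads, "qual")))
  # processing the re-imported reads gives the same count table
  p1 <- process_reads(reads, arch)
  p2 <- process_reads(back, arch)
  expect_equal(as.data.frame(p1$counts[order(p1$counts$barcode), ]),
               as.data.frame(p2$counts[order(p2$counts$barcode), ]),
               ignore_attr = TRUE)
})
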