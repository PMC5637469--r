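# Independent reference implementations used as oracles, plus tiny
# fixtures built in code. These deliberately use naive loops so they share
# no code path with the package internals they check.

# Small architecture: 6 nt primers, 2 nt barcode, spike "GA" carrying a
# 2 nt "digest site".
tiny_arch <- function() {
  library_architecture(primer5 = "ACGTGC", primer3 = "TGCACG",
                       barcode_length = 2L, spike_barcode = "GA",
                       digest_site = "GA", digest_site_offset = 0L)
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive reference for pair merging: same documented rules, written as
# plain loops over characters and offsets.
oracle_merge <- function(r1, r2, q1, q2, min_overlap, max_mismatch_frac) {
  s2 <- oracle_revcomp(r2)
  u2 <- rev(q2)
  c1 <- strsplit(r1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  len1 <- length(c1); len2 <- length(c2)
  cand <- list(); any_best <- NULL
  for (d in seq(-(len2 - min_overlap), len1 - min_overlap)) {
    lo <- max(1, d + 1); hi <- min(len1, d + len2)
    ov <- hi - lo + 1
    if (ov < min_overlap) next
    i <- lo:hi
    match <- sum(c1[i] == c2[i - d])
    mm <- ov - match
    entry <- list(d = d, ov = ov, match = match, mm = mm)
    better <- function(a, b) {
      is.null(b) || a$match > b$match || (a$match == b$match && a$mm < b$mm)
    }
    if (better(entry, any_best)) any_best <- entry
    if (mm / ov <= max_mismatch_frac && better(entry, cand$best))
      cand$best <- entry
  }
  if (is.null(cand$best)) {
    status <- if (!is.null(any_best) && any_best$match >= min_overlap)
      "too_many_mismatches" else "no_overlap"
    return(list(status = status, consensus = NA_character_))
  }
  b <- cand$best; d <- b$d
  cons <- character(d + len2); qual <- integer(d + len2)
  for (i in seq_len(d + len2)) {
    in1 <- i <= len1
    in2 <- i - d >= 1
    if (in1 && in2) {
      if (c1[i] == c2[i - d] || q1[i] >= u2[i - d]) {
        cons[i] <- c1[i]; qual[i] <- max(q1[i], u2[i - d])
      } else {
        cons[i] <- c2[i - d]; qual[i] <- u2[i - d]
      }
    } else if (in1) {
      cons[i] <- c1[i]; qual[i] <- q1[i]
    } else {
      cons[i] <- c2[i - d]; qual[i] <- u2[i - d]
    }
  }
  list(status = "merged", consensus = paste(cons, collapse = ""),
       overlap_len = b$ov, n_mismatch = b$mm, qual = qual)
}

# Naive reference for fold enrichment: one barcode at a time.
oracle_fold_enrichment <- function(pre, post, alpha) {
  bars <- union(pre$barcode, post$barcode)
  K <- length(bars)
  n1 <- sum(pre$count); n2 <- sum(post$count)
  out <- data.frame(barcode = bars, enrichment = NA_real_)
  for (i in seq_along(bars)) {
    a <- pre$count[pre$barcode == bars[i]]
    if (length(a) == 0) a <- 0
    b <- post$count[post$barcode == bars[i]]
    if (length(b) == 0) b <- 0
    f_pre <- (a + alpha) / (n1 + alpha * K)
    f_post <- (b + alpha) / (n2 + alpha * K)
    out$enrichment[i] <- f_post / f_pre
  }
  out
}

# Enumerate the full barcode space for small lengths.
enumerate_barcodes <- function(length) {
  if (length == 0) return("")
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), length))
  sort(apply(grid[rev(seq_len(length))], 1, paste, collapse = ""))
}

make_read_pair <- function(r1, r2, q1 = NULL, q2 = NULL, quality = 30L) {
  if (is.null(q1)) q1 <- rep(quality, nchar(r1))
  if (is.null(q2)) q2 <- rep(quality, nchar(r2))
  structure(list(r1_seq = r1, r2_seq = r2,
                 r1_qual = as.integer(q1), r2_qual = as.integer(q2),
                 origin_barcode = NULL),
            class = "read_pair")
}
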