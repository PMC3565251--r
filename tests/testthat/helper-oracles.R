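# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no IRanges, no hamming_sites): per-base labeling,
# character-by-character comparison, exhaustive enumeration.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# per-base coverage fraction of [start, end) (0-based) by intervals of the
# given classes
oracle_coverage <- function(intervals, chrom, start, end, classes) {
  covered <- logical(end - start)
  sel <- intervals$chrom == chrom & intervals$rep_class %in% classes
  for (i in which(sel)) {
    s <- max(intervals$start[i], start)
    e <- min(intervals$end[i], end)
    if (s < e) covered[(s - start + 1):(e - start)] <- TRUE
  }
  mean(covered)
}

# naive scan: label every base, test every window, merge runs by hand
oracle_scan <- function(intervals, chrom, chrom_length, cfg) {
  if (cfg$window > chrom_length) return(NULL)
  sat <- logical(chrom_length)
  int <- logical(chrom_length)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != chrom) next
    idx <- (intervals$start[i] + 1):intervals$end[i]
    if (intervals$rep_class[i] %in% cfg$satellite_classes) sat[idx] <- TRUE
    if (intervals$rep_class[i] %in% cfg$interspersed_classes) int[idx] <- TRUE
  }
  starts <- seq(0, chrom_length - cfg$window, by = cfg$step)
  ok <- vapply(starts, function(s) {
    w <- (s + 1):(s + cfg$window)
    mean(sat[w]) >= cfg$min_satellite_fraction &&
      mean(int[w]) <= cfg$max_interspersed_fraction
  }, logical(1))
  if (!any(ok)) return(data.frame(start = numeric(0), end = numeric(0)))
  # merge overlapping/abutting qualifying windows
  qs <- starts[ok]
  qe <- qs + cfg$window
  merged <- list(c(qs[1], qe[1]))
  for (i in seq_along(qs)[-1]) {
    last <- merged[[length(merged)]]
    if (qs[i] <= last[2]) {
      merged[[length(merged)]][2] <- max(last[2], qe[i])
    } else {
      merged[[length(merged) + 1]] <- c(qs[i], qe[i])
    }
  }
  out <- do.call(rbind, lapply(merged, function(x)
    data.frame(start = x[1], end = x[2])))
  out <- out[out$end - out$start >= cfg$min_region_length, , drop = FALSE]
  keep <- vapply(seq_len(nrow(out)), function(i) {
    s <- oracle_coverage(intervals, chrom, out$start[i], out$end[i],
                         cfg$satellite_classes)
    it <- oracle_coverage(intervals, chrom, out$start[i], out$end[i],
                          cfg$interspersed_classes)
    s >= cfg$min_satellite_fraction && it <= cfg$max_interspersed_fraction
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive primer-site search by direct substring comparison
oracle_sites <- function(template, pattern, max_mismatch = 0) {
  n <- nchar(template)
  m <- nchar(pattern)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  hits <- integer(0)
  mms <- integer(0)
  for (s in seq_len(n - m + 1)) {
    sub <- strsplit(substr(template, s, s + m - 1), "", fixed = TRUE)[[1]]
    mm <- sum(sub != pat | sub == "N" | pat == "N")
    if (mm <= max_mismatch) {
      hits <- c(hits, s)
      mms <- c(mms, mm)
    }
  }
  data.frame(start = hits, mismatches = mms)
}

# all-pairs amplicon enumeration from oracle sites
oracle_ispcr <- function(template, fwd, rev, max_mismatch = 0,
                         max_product = 5000) {
  fs <- oracle_sites(template, fwd, max_mismatch)
  rs <- oracle_sites(template, oracle_revcomp(rev), max_mismatch)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      f <- fs$start[i]
      pend <- rs$start[j] + nchar(rev) - 1
      len <- pend - f + 1
      if (f <= rs$start[j] && f + nchar(fwd) - 1 <= pend &&
          len <= max_product) {
        out[[length(out) + 1]] <- data.frame(start = f, end = pend,
                                             length = len)
      }
    }
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0),
                                      length = numeric(0)))
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# count motif occurrences in a primer by direct comparison, both strands
oracle_motif_count <- function(primer, motif) {
  nrow(oracle_sites(primer, motif)) +
    if (oracle_revcomp(motif) != motif) {
      nrow(oracle_sites(primer, oracle_revcomp(motif)))
    } else 0
}

# slide every probe k-mer over every chromosome, counting both strands
oracle_kmer_hits <- function(probe, genome_seqs, k) {
  kms <- unique(unlist(lapply(seq_len(nchar(probe) - k + 1), function(i) {
    km <- substr(probe, i, i + k - 1)
    if (grepl("N", km, fixed = TRUE)) return(character(0))
    c(km, oracle_revcomp(km))
  })))
  vapply(genome_seqs, function(s) {
    n <- nchar(s)
    hits <- 0
    for (p in seq_len(n - k + 1)) {
      gk <- substr(s, p, p + k - 1)
      if (!grepl("N", gk, fixed = TRUE) && gk %in% kms) hits <- hits + 1
    }
    hits
  }, numeric(1))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
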