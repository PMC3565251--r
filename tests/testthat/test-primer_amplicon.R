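test_that("consensus_homology counts motif occurrences and footprint coverage", {
  expect_equal(consensus_homology("TTCCA"),
               c(match_count = 1, coverage = 1))
  expect_equal(consensus_homology("AAAAAAAAAA"),
               c(match_count = 0, coverage = 0))
  # both printed primers against the independent brute-force scan
  for (p in c(WYR4, WYR6)) {
    expect_equal(consensus_homology(p)[["match_count"]],
                 oracle_motif_count(p, "TTCCA"))
  }
  expect_gt(consensus_homology(WYR6)[["match_count"]],
            consensus_homology(WYR4)[["match_count"]])
  # reverse-complement motif counts when both_strands
  expect_equal(consensus_homology("AATGGAAAAA")[["match_count"]], 1)
  expect_equal(
    consensus_homology("AATGGAAAAA",
                       consensus_motif(both_strands = FALSE))[["match_count"]],
    0)
  expect_error(consensus_homology("TTC"), "shorter than motif")
})

test_that("consensus_homology is strand-symmetric under both_strands", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_dna_str(sample(10:40, 1))
    expect_equal(consensus_homology(p), consensus_homology(revcomp(p)),
                 info = p)
  }
})

test_that("gc_fraction and tm_wallace are the stated closed forms", {
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(tm_wallace("ACGT"), 12)
  expect_equal(gc_fraction("GGGG"), 1)
  expect_equal(tm_wallace("GGGG"), 16)
  # independent per-base tally of the printed forward primer
  b <- strsplit(WYR4, "")[[1]]
  expect_equal(gc_fraction(WYR4), sum(b %in% c("G", "C")) / length(b))
  expect_equal(tm_wallace(WYR4),
               2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  expect_error(gc_fraction("ACGN"), "N in primer")
  expect_error(tm_wallace("ACGN"), "N in primer")
})

test_that("enumerate_primers prefers a planted low-consensus island", {
  set.seed(4)
  island <- "GCAGTCGACGGATCGCGATAGCTGACGGTACGATCGATCG"  # 40 bp, motif-free
  mono <- paste0(strrep("TTCCA", 60), island, strrep("TTCCA", 40))
  got <- enumerate_primers(mono, length_range = 20)
  top <- got[1, ]
  expect_equal(top$consensus_match_count, 0)
  expect_equal(top$consensus_coverage, 0)
  # footprint confined to the island (up to 4 flanking bases that cannot
  # complete a motif occurrence)
  expect_gte(top$template_start, 296)
  expect_lte(top$template_start + top$length, 344)
  expect_error(enumerate_primers("ACGTACGT", length_range = 20), "shorter")
  expect_error(enumerate_primers(mono, length_range = integer(0)), "empty")
})

test_that("enumerate_primers ranking equals an exhaustive independent sort", {
  set.seed(14)
  mono <- random_dna_str(300)
  got <- enumerate_primers(mono, length_range = 20)
  # independent enumeration + scoring + ordering
  L <- 20
  rows <- list()
  for (s0 in 0:(nchar(mono) - L)) {
    fwd <- substr(mono, s0 + 1, s0 + L)
    for (strand in c("+", "-")) {
      sq <- if (strand == "+") fwd else oracle_revcomp(fwd)
      cnt <- oracle_motif_count(sq, "TTCCA")
      covered <- logical(L)
      for (m in c("TTCCA", "TGGAA")) {
        st <- oracle_sites(sq, m)$start
        for (s in st) covered[s:(s + 4)] <- TRUE
      }
      b <- strsplit(sq, "")[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        sequence = sq, template_start = s0, strand = strand, length = L,
        consensus_match_count = cnt, consensus_coverage = mean(covered),
        gc_fraction = sum(b %in% c("G", "C")) / L)
    }
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle$consensus_coverage,
                         oracle$consensus_match_count,
                         abs(oracle$gc_fraction - 0.5),
                         oracle$template_start, oracle$strand), ]
  expect_equal(got$sequence, oracle$sequence)
  expect_equal(got$consensus_match_count, oracle$consensus_match_count)
  # repeated runs are identical (deterministic total order)
  expect_identical(got, enumerate_primers(mono, length_range = 20))
})

test_that("GC/Tm constraints filter before ranking", {
  set.seed(2)
  mono <- random_dna_str(200)
  got <- enumerate_primers(mono, length_range = 18, gc_min = 0.4,
                           gc_max = 0.6, tm_min = 50)
  expect_true(all(got$gc_fraction >= 0.4 & got$gc_fraction <= 0.6))
  expect_true(all(got$tm_wallace >= 50))
})

test_that("insilico_pcr reproduces the published amplicon geometry", {
  mono <- dyz1_like_monomer(1)
  expect_equal(mono$length, 3564)
  amp <- insilico_pcr(mono, WYR4, WYR6, max_mismatch = 0)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 2965)
  expect_equal(amp$end, 3212)
  expect_equal(amp$length, 248)
  # primers with no match anywhere -> empty
  none <- insilico_pcr(mono, "GGGGGGGGGGGGGGGGGG", "CCCCCCCCCCCCCCCCCC")
  expect_equal(nrow(none), 0)
})

test_that("insilico_pcr equals the exhaustive all-pairs oracle on tandem templates", {
  mono <- dyz1_like_monomer(3)
  tmpl <- seq_record("tandem10", strrep(mono$sequence, 10))
  got <- insilico_pcr(tmpl, WYR4, WYR6, max_product = 5000)
  oracle <- oracle_ispcr(tmpl$sequence, WYR4, WYR6, max_product = 5000)
  expect_equal(got[, c("start", "end", "length")], oracle)
  expect_gt(nrow(got), 1)  # cross-copy products under the size cap
  # invariants: length arithmetic and footprint containment
  expect_equal(got$length, got$end - got$start + 1)
  expect_true(all(got$fwd_start >= got$start &
                    got$fwd_start + nchar(WYR4) - 1 <= got$end))
  expect_true(all(got$rev_start >= got$start &
                    got$rev_start + nchar(WYR6) - 1 <= got$end))
})

test_that("insilico_pcr tolerates mismatches only up to the allowance", {
  set.seed(31)
  tmpl <- random_dna_str(2000)
  fwd <- substr(tmpl, 101, 124)
  rev <- oracle_revcomp(substr(tmpl, 501, 524))
  # corrupt one base of the forward site
  t2 <- paste0(substr(tmpl, 1, 109),
               chartr("ACGT", "CATG", substr(tmpl, 110, 110)),
               substr(tmpl, 111, 2000))
  expect_equal(nrow(insilico_pcr(t2, fwd, rev, max_mismatch = 0)), 0)
  amp <- insilico_pcr(t2, fwd, rev, max_mismatch = 1)
  expect_equal(amp$start, 101)
  expect_equal(amp$end, 524)
  expect_equal(amp$fwd_mismatches, 1)
  expect_equal(amp$rev_mismatches, 0)
  expect_equal(amp[, c("start", "end", "length")],
               oracle_ispcr(t2, fwd, rev, max_mismatch = 1))
})

test_that("N never matches a primer position", {
  tmpl <- paste0(strrep("A", 50), "NNNN", strrep("A", 50))
  expect_equal(nrow(insilico_pcr(tmpl, "AAAAANAAAA", "TTTTTTTTTT",
                                 max_mismatch = 0)), 0)
  sites <- satprobe:::hamming_sites(tmpl, "AAAAAAAAAA", 0)
  expect_false(any(sites$start > 41 & sites$start <= 54))
})
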