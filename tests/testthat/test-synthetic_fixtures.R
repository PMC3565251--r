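toy_spec <- function(seed = 101, divergence = 0) {
  fixture_spec(
    seed = seed,
    chromosomes = data.frame(name = c("chrA", "chrB"),
                             length = c(200000, 80000)),
    planted_arrays = list(
      list(chrom = "chrA", start = 60000, monomer = strrep("TTCCA", 100),
           copies = 100, divergence = divergence, name = "SAT_A")),
    interspersed_elements = list(
      list(chrom = "chrB", start = 10000, length = 300, class = "SINE")),
    clone_placements = list(
      list(name = "cl_in", chrom = "chrA", start = 70000, end = 100000),
      list(name = "cl_out", chrom = "chrA", start = 150000, end = 180000)),
    primer_plants = list(
      list(chrom = "chrB", primer = "GATTACAGATTACAGATTACAGAT",
           position = 30000, strand = "+"),
      list(chrom = "chrB", primer = "CTGCGTGCTAGCTAGCCGATTGCA",
           position = 30500, strand = "-")))
}

test_that("fixture generation is byte-deterministic", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(toy_spec(), d1)
  generate_fixture(toy_spec(), d2)
  for (f in c("genome.fasta", "repeats.out", "clones.tsv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  generate_fixture(toy_spec(seed = 202), d3)
  expect_false(identical(readBin(file.path(d1, "genome.fasta"), "raw", 1e7),
                         readBin(file.path(d3, "genome.fasta"), "raw", 1e7)))
})

test_that("zero planted features give a pure random genome with empty annotation", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 5,
                       chromosomes = data.frame(name = "c", length = 5000))
  res <- generate_fixture(spec, d)
  expect_equal(nrow(res$annotation), 0)
  expect_equal(nrow(res$clones), 0)
  expect_equal(res$genome[[1]]$length, 5000)
  expect_equal(nrow(parse_repeatmasker_out(res$paths[["annotation"]])), 0)
})

test_that("divergence model plants exact copies at 0 and binomial noise otherwise", {
  d <- withr::local_tempdir()
  mono <- strrep("TTCCA", 1)  # 5-mer monomer, 20 copies
  spec0 <- fixture_spec(seed = 7,
                        chromosomes = data.frame(name = "c", length = 1000),
                        planted_arrays = list(
                          list(chrom = "c", start = 400, monomer = mono,
                               copies = 20, divergence = 0)))
  res0 <- generate_fixture(spec0, d)
  got <- substr(res0$genome[[1]]$sequence, 401, 500)
  expect_equal(got, strrep("TTCCA", 20))
  expect_equal(res0$manifest$arrays[[1]]$n_substitutions, 0)

  spec1 <- fixture_spec(seed = 8,
                        chromosomes = data.frame(name = "c", length = 60000),
                        planted_arrays = list(
                          list(chrom = "c", start = 1000,
                               monomer = strrep("TTCCA", 100), copies = 100,
                               divergence = 0.1)))
  res1 <- generate_fixture(spec1, d)
  arr <- res1$manifest$arrays[[1]]
  n <- 50000
  observed <- arr$n_substitutions / n
  # within 3 binomial standard deviations of the nominal rate
  expect_lt(abs(observed - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # realized mismatch positions agree with the emitted sequence
  raw <- strrep("TTCCA", 100 * 100)
  got1 <- substr(res1$genome[[1]]$sequence, 1001, 1000 + n)
  diff_pos <- which(strsplit(got1, "")[[1]] != strsplit(raw, "")[[1]])
  expect_equal(diff_pos - 1L, sort(arr$substitution_offsets))
})

test_that("overlapping planted features are rejected with the collision named", {
  expect_error(
    fixture_spec(seed = 1,
                 chromosomes = data.frame(name = "c", length = 10000),
                 planted_arrays = list(
                   list(chrom = "c", start = 100, monomer = "TTCCA",
                        copies = 100, divergence = 0),
                   list(chrom = "c", start = 500, monomer = "TTCCA",
                        copies = 10, divergence = 0))),
    "overlap")
  expect_error(
    fixture_spec(seed = 1,
                 chromosomes = data.frame(name = "c", length = 100),
                 planted_arrays = list(
                   list(chrom = "c", start = 50, monomer = "TTCCA",
                        copies = 100, divergence = 0))),
    "bounds")
})

test_that("truth closure: scan, select and ispcr reproduce the manifest", {
  d <- withr::local_tempdir()
  res <- generate_fixture(toy_spec(), d)
  man <- res$manifest

  ann <- parse_repeatmasker_out(res$paths[["annotation"]])
  regions <- scan_candidate_regions(ann[ann$chrom == "chrA", ], 200000,
                                    scan_config())
  expect_equal(nrow(regions), length(man$expected_regions))
  exp_r <- man$expected_regions[[1]]
  # recovered span contains the planted array, within one window of slack
  expect_lte(abs(regions$start - exp_r$start), 10000)
  expect_lte(abs(regions$end - exp_r$end), 10000)
  expect_equal(regions$dominant_rep_name, exp_r$dominant_rep_name)

  clones <- parse_clone_table(res$paths[["clones"]])
  sel <- select_clones(clones, list(chrom = exp_r$chrom,
                                    start = exp_r$start, end = exp_r$end))
  expect_equal(sel$name, man$expected_selected_clones)

  genome <- read_fasta(res$paths[["fasta"]])
  chrB <- genome[[which(vapply(genome, `[[`, character(1), "id") == "chrB")]]
  amp <- insilico_pcr(chrB, "GATTACAGATTACAGATTACAGAT",
                      "CTGCGTGCTAGCTAGCCGATTGCA")
  expect_equal(nrow(amp), length(man$expected_amplicons))
  expect_equal(amp$start, man$expected_amplicons[[1]]$start)
  expect_equal(amp$end, man$expected_amplicons[[1]]$end)
  expect_equal(amp$length, man$expected_amplicons[[1]]$length)

  # annotation and manifest agree feature-for-feature
  expect_equal(nrow(ann),
               length(man$arrays) + length(man$interspersed_elements))
})

test_that("the DYZ1-like monomer satisfies its documented geometry", {
  mono <- dyz1_like_monomer(2)
  expect_equal(mono$length, 3564)
  amp <- insilico_pcr(mono, WYR4, WYR6)
  expect_equal(amp[, c("start", "end", "length")],
               data.frame(start = 2965, end = 3212, length = 248))
  # planted island scores lower consensus homology than background windows
  island <- substr(mono$sequence, 1001, 1040)
  background <- substr(mono$sequence, 101, 140)
  expect_lt(consensus_homology(island)[["match_count"]],
            consensus_homology(background)[["match_count"]])
  expect_equal(consensus_homology(island)[["match_count"]], 0)
  # determinism across calls
  expect_identical(dyz1_like_monomer(2), mono)
})
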