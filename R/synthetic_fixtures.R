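#' @title Synthetic genome fixtures with planted truth
#' @description Deterministic toy genomes for end-to-end testing without
#'   any download: seeded-uniform random background with planted tandem
#'   satellite arrays (i.i.d. per-base substitution divergence, no indels,
#'   so planted coordinates stay exact), interspersed repeat elements,
#'   primer binding sites and BAC clone placements, plus a machine-readable
#'   truth manifest carrying the expected downstream answers.
#' @name synthetic-fixtures
NULL

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream; a single integer seed governs all randomness of a fixture.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate`; returns the
# mutated string and the 1-based positions touched
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(list(sequence = x, positions = integer(0)))
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  idx <- which(stats::runif(length(b)) < rate & b != "N")
  for (i in idx) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  }
  list(sequence = paste(b, collapse = ""), positions = idx)
}

#' Fixture specification
#'
#' Coordinates throughout are the internal 0-based half-open convention.
#' Sequence-altering features (arrays, interspersed elements, primer
#' plants) must fit in their chromosome and must not overlap one another;
#' clone placements are annotation-only and may (deliberately) lie inside
#' planted arrays.
#'
#' @param seed single integer governing all randomness.
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param planted_arrays list of lists: `chrom`, `start`, `monomer` (DNA
#'   string), `copies`, `divergence` (per-base substitution rate in
#'   `[0, 1]`), optional `name`.
#' @param interspersed_elements list of lists: `chrom`, `start`, `length`,
#'   `class` (e.g. "SINE"), optional `name`.
#' @param clone_placements list of lists: `name`, `chrom`, `start`, `end`.
#' @param primer_plants list of lists: `chrom`, `primer`, `position`,
#'   `strand` ("+" writes the primer, "-" writes its reverse complement).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, chromosomes,
                         planted_arrays = list(),
                         interspersed_elements = list(),
                         clone_placements = list(),
                         primer_plants = list()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  spec <- structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                         planted_arrays = planted_arrays,
                         interspersed_elements = interspersed_elements,
                         clone_placements = clone_placements,
                         primer_plants = primer_plants),
                    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

feature_spans <- function(spec) {
  spans <- list()
  for (a in spec$planted_arrays) {
    len <- nchar(a$monomer) * a$copies
    spans[[length(spans) + 1L]] <- list(
      chrom = a$chrom, start = a$start, end = a$start + len,
      what = sprintf("array@%s:%d", a$chrom, a$start))
  }
  for (e in spec$interspersed_elements) {
    spans[[length(spans) + 1L]] <- list(
      chrom = e$chrom, start = e$start, end = e$start + e$length,
      what = sprintf("element@%s:%d", e$chrom, e$start))
  }
  for (p in spec$primer_plants) {
    spans[[length(spans) + 1L]] <- list(
      chrom = p$chrom, start = p$position,
      end = p$position + nchar(p$primer),
      what = sprintf("plant@%s:%d", p$chrom, p$position))
  }
  spans
}

validate_fixture_spec <- function(spec) {
  clen <- stats::setNames(spec$chromosomes$length, spec$chromosomes$name)
  spans <- feature_spans(spec)
  for (s in spans) {
    if (!s$chrom %in% names(clen)) {
      stop("unknown chromosome in ", s$what, call. = FALSE)
    }
    if (s$start < 0 || s$end > clen[[s$chrom]]) {
      stop("feature outside chromosome bounds: ", s$what, call. = FALSE)
    }
  }
  if (length(spans) > 1L) {
    for (i in seq_len(length(spans) - 1L)) {
      for (j in (i + 1L):length(spans)) {
        a <- spans[[i]]; b <- spans[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          stop(sprintf("planted features overlap: %s vs %s", a$what, b$what),
               call. = FALSE)
        }
      }
    }
  }
  for (cl in spec$clone_placements) {
    if (!cl$chrom %in% names(clen) || cl$start < 0 ||
        cl$end > clen[[cl$chrom]] || cl$start >= cl$end) {
      stop("invalid clone placement: ", cl$name, call. = FALSE)
    }
  }
  invisible(spec)
}

splice <- function(sequence, start0, insert) {
  paste0(substr(sequence, 1L, start0),
         insert,
         substr(sequence, start0 + nchar(insert) + 1L, nchar(sequence)))
}

#' Generate a fixture genome with its truth manifest
#'
#' Emits a multi-record FASTA, a RepeatMasker-dialect annotation covering
#' exactly the planted features, a clone placement TSV (1-based inclusive,
#' insert = span) and a JSON truth manifest. Same spec + seed gives
#' byte-identical files.
#'
#' The manifest also records the expected downstream answers under default
#' configurations: `expected_regions` (planted satellite arrays at least
#' the default minimum region length, no interspersed contamination by
#' construction), `expected_selected_clones` (clones contained in an
#' expected region) and `expected_amplicons` (all valid pairings of
#' planted forward/reverse primer sites within the default product-size
#' cap), computed from the plant geometry, not by running the pipeline.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return invisibly, a list: `genome` (list of [seq_record]),
#'   `annotation` (repeat-interval data.frame), `clones` (clone table),
#'   `manifest` (list), `paths` (named character).
#' @export
generate_fixture <- function(spec, dir) {
  validate_fixture_spec(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(spec$seed, {
    genome <- list()
    arrays <- list()
    # chromosomes in spec order; features applied in spec order
    for (ci in seq_len(nrow(spec$chromosomes))) {
      cname <- spec$chromosomes$name[[ci]]
      seqn <- random_dna(spec$chromosomes$length[[ci]])
      for (a in spec$planted_arrays) {
        if (a$chrom != cname) next
        raw <- strrep(normalize_dna(a$monomer, "monomer"), a$copies)
        mut <- mutate_dna(raw, a$divergence)
        seqn <- splice(seqn, a$start, mut$sequence)
        arrays[[length(arrays) + 1L]] <- list(
          name = if (!is.null(a$name)) a$name else
            sprintf("SAT_%s_%d", cname, a$start),
          chrom = cname, start = a$start, end = a$start + nchar(raw),
          monomer_length = nchar(a$monomer), copies = a$copies,
          divergence = a$divergence,
          n_substitutions = length(mut$positions),
          substitution_offsets = mut$positions - 1L)
      }
      for (e in spec$interspersed_elements) {
        if (e$chrom != cname) next
        seqn <- splice(seqn, e$start, random_dna(e$length))
      }
      for (p in spec$primer_plants) {
        if (p$chrom != cname) next
        ins <- if (p$strand == "-") revcomp(p$primer) else
          normalize_dna(p$primer, "primer plant")
        seqn <- splice(seqn, p$position, ins)
      }
      genome[[length(genome) + 1L]] <- seq_record(cname, seqn)
    }
    list(genome = genome, arrays = arrays)
  })
  genome <- res$genome
  arrays <- res$arrays

  ann_rows <- list()
  for (a in arrays) {
    ann_rows[[length(ann_rows) + 1L]] <-
      repeat_intervals(a$chrom, a$start, a$end, "+", a$name,
                       "Satellite", "SAT")
  }
  for (e in spec$interspersed_elements) {
    ann_rows[[length(ann_rows) + 1L]] <-
      repeat_intervals(e$chrom, e$start, e$start + e$length, "+",
                       if (!is.null(e$name)) e$name else
                         sprintf("%s_sim", e$class),
                       e$class, "sim")
  }
  annotation <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    repeat_intervals()

  clones <- if (length(spec$clone_placements)) {
    do.call(rbind, lapply(spec$clone_placements, function(cl) {
      data.frame(name = cl$name, chrom = cl$chrom, band = "-",
                 start = cl$start + 1, end = cl$end,
                 insert_size = cl$end - cl$start,
                 accessions = "SYNTHETIC", multi_mapping = FALSE,
                 stringsAsFactors = FALSE)
    }))
  } else empty_clone_table()

  manifest <- build_manifest(spec, arrays, clones)

  paths <- c(fasta = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "repeats.out"),
             clones = file.path(dir, "clones.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta(genome, paths[["fasta"]])
  write_repeatmasker_out(annotation, paths[["annotation"]])
  write_clone_table(clones, paths[["clones"]])
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome = genome, annotation = annotation, clones = clones,
                 manifest = manifest, paths = paths))
}

build_manifest <- function(spec, arrays, clones) {
  cfg <- scan_config()
  expected_regions <- lapply(
    Filter(function(a) a$end - a$start >= cfg$min_region_length, arrays),
    function(a) list(chrom = a$chrom, start = a$start, end = a$end,
                     dominant_rep_name = a$name))
  expected_clones <- character(0)
  for (i in seq_len(nrow(clones))) {
    for (r in expected_regions) {
      if (strip_chr(clones$chrom[i]) == strip_chr(r$chrom) &&
          clones$start[i] - 1 >= r$start && clones$end[i] <= r$end) {
        expected_clones <- c(expected_clones, clones$name[i])
      }
    }
  }
  expected_amplicons <- list()
  plants <- spec$primer_plants
  for (f in plants) {
    if (f$strand != "+") next
    for (r in plants) {
      if (r$strand != "-" || r$chrom != f$chrom) next
      p_start <- f$position + 1
      p_end <- r$position + nchar(r$primer)
      len <- p_end - p_start + 1
      if (f$position <= r$position &&
          f$position + nchar(f$primer) <= p_end && len <= 5000) {
        expected_amplicons[[length(expected_amplicons) + 1L]] <-
          list(template_id = f$chrom, start = p_start, end = p_end,
               length = len)
      }
    }
  }
  list(seed = spec$seed,
       chromosomes = spec$chromosomes,
       arrays = arrays,
       interspersed_elements = spec$interspersed_elements,
       clones = clones,
       primer_plants = plants,
       expected_regions = expected_regions,
       expected_selected_clones = unique(expected_clones),
       expected_amplicons = expected_amplicons)
}

#' Write intervals in the RepeatMasker .out dialect
#'
#' Two header lines and one blank line, then whitespace-separated columns
#' with 1-based inclusive query coordinates, strand "C" for minus.
#'
#' @param intervals repeat-interval data.frame (internal coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(intervals, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste("  SW   perc perc perc  query     position in query",
                     "matching repeat"),
               paste("score   div. del. ins.  sequence  begin end (left)",
                     "repeat class/family begin end (left) ID"),
               ""), con)
  for (i in seq_len(nrow(intervals))) {
    cf <- if (nzchar(intervals$rep_family[i])) {
      paste0(intervals$rep_class[i], "/", intervals$rep_family[i])
    } else intervals$rep_class[i]
    writeLines(sprintf("%5d %5.1f %4.1f %4.1f %s %d %d (%d) %s %s %s %d %d (%d) %d",
                       1000L, 0.0, 0.0, 0.0, intervals$chrom[i],
                       as.integer(intervals$start[i]) + 1L,
                       as.integer(intervals$end[i]), 0L,
                       if (intervals$strand[i] == "-") "C" else "+",
                       intervals$rep_name[i], cf, 1L,
                       as.integer(intervals$end[i] - intervals$start[i]),
                       0L, i), con)
  }
  invisible(path)
}

#' Write a clone placement table
#'
#' Tab-separated, same column order [parse_clone_table] reads; no
#' thousands separators on machine-readable output.
#'
#' @param clones clone table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("BAC\tChr\tBand\tStart\tEnd\tInsert\tAccessions", con)
  for (i in seq_len(nrow(clones))) {
    s <- if (clones$multi_mapping[i]) "multiple" else
      sprintf("%d", as.integer(clones$start[i]))
    e <- if (clones$multi_mapping[i]) "multiple" else
      sprintf("%d", as.integer(clones$end[i]))
    writeLines(paste(clones$name[i], clones$chrom[i], clones$band[i], s, e,
                     sprintf("%d", as.integer(clones$insert_size[i])),
                     clones$accessions[i], sep = "\t"), con)
  }
  invisible(path)
}

#' Packaged clone table transcribing the published six-clone selection
#'
#' The six BAC rows (names, chromosomes, bands, coordinates with comma
#' separators, insert sizes, end-sequence accessions) for the satellite-
#' rich regions of chromosomes X, Y and 16, including the multi-mapping
#' Y-heterochromatin clone whose coordinate fields read "multiple".
#'
#' @param path optional destination; the packaged file is copied there.
#' @return path to the TSV (the installed copy when `path` is `NULL`).
#' @export
table1_fixture <- function(path = NULL) {
  src <- system.file("extdata", "published_clone_table.tsv",
                     package = "satprobe", mustWork = TRUE)
  if (is.null(path)) return(src)
  file.copy(src, path, overwrite = TRUE)
  path
}

# pentamer variant pool for satellite-III-like background: the consensus
# plus single-substitution neighbours
.PENTAMER_VARIANTS <- c("TTCCA", "TTCCT", "TTCCG", "TTCAA", "TTACA",
                        "TACCA", "CTCCA", "GTCCA")

#' Synthetic Y-heterochromatin-like repeat monomer
#'
#' A 3,564 bp stand-in for the DYZ1 repeat monomer: a pentanucleotide
#' (TTCCA-family) background with (i) a planted 40 bp low-consensus island
#' (no TTCCA/TGGAA occurrence) at offset 1000, (ii) the printed forward
#' primer [WYR4] planted so its 5' end sits at template position 2965
#' (1-based) and (iii) the reverse-complemented [WYR6] site ending at
#' position 3212 — reproducing the published 248 bp amplicon geometry.
#' The construction verifies each primer site is unique on the monomer
#' and deterministically re-draws the background otherwise, so
#' [insilico_pcr] at zero mismatches always reports exactly one product.
#' This sequence is synthetic; only its length and primer-site geometry
#' follow the published repeat.
#'
#' @param seed integer seed.
#' @return a [seq_record] of length 3564, id `"DYZ1_like_synthetic"`.
#' @export
dyz1_like_monomer <- function(seed = 1L) {
  total <- 3564L
  island_start0 <- 1000L
  island_len <- 40L
  fwd_start0 <- 2964L                     # printed position 2965, 1-based
  rev_end1 <- 3212L
  rev_start0 <- rev_end1 - nchar(WYR6)    # 3185: rc site at 3186..3212
  for (attempt in 0:99) {
    seqn <- with_seed(seed + attempt * 7919L, {
      n_pent <- ceiling(total / 5L)
      # consensus-heavy mixture: draws lean on the exact TTCCA pentamer
      pents <- sample(.PENTAMER_VARIANTS, n_pent, replace = TRUE,
                      prob = c(0.6, rep(0.4 / 7, 7)))
      s <- substr(paste(pents, collapse = ""), 1L, total)
      island <- random_dna(island_len)
      while (grepl("TTCCA", island, fixed = TRUE) ||
             grepl("TGGAA", island, fixed = TRUE)) {
        island <- random_dna(island_len)
      }
      s <- splice(s, island_start0, island)
      s <- splice(s, fwd_start0, WYR4)
      splice(s, rev_start0, revcomp(WYR6))
    })
    if (nrow(hamming_sites(seqn, WYR4)) == 1L &&
        nrow(hamming_sites(seqn, revcomp(WYR6))) == 1L &&
        nrow(hamming_sites(seqn, revcomp(WYR4))) == 0L &&
        nrow(hamming_sites(seqn, WYR6)) == 0L) {
      return(seq_record("DYZ1_like_synthetic", seqn))
    }
  }
  stop("could not realize a monomer with unique primer sites", call. = FALSE)
}
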