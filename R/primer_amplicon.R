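#' @title Repeat-targeting primer design and in-silico PCR
#' @description Scores primer candidates on a satellite monomer for
#'   homology to a consensus motif (lower is better: primers that sit in
#'   diverged islands of the monomer amplify the target repeat without
#'   cross-hybridizing to related satellite families), plus standard GC /
#'   Wallace-rule melting temperature QC, and predicts PCR products by
#'   exact or Hamming-mismatch site matching on a template.
#' @name primer-amplicon
NULL

#' Printed Y-repeat primers and BLAST query
#'
#' The historical primer pair amplifying a 248 bp product from the DYZ1
#' Y-heterochromatin repeat monomer, and the 27-nt query used for a
#' genome-wide homology screen. Carried as named constants.
#' @format character scalars.
#' @export
WYR4 <- "GAACCGTACGATTCCATTCCTTTTGAA"

#' @rdname WYR4
#' @export
WYR6 <- "TTCCATTCCATTCCATTCCTTTCCTTT"

#' @rdname WYR4
#' @export
Y_QUERY_27NT <- "ATTCCGTACGATTCCATTCCTTTTGAA"

#' Consensus motif
#'
#' @param motif DNA motif, length >= 2, alphabet A/C/G/T. Default is the
#'   human satellite III consensus pentamer.
#' @param both_strands if `TRUE` (default), the reverse complement of the
#'   motif also counts as a match, making homology scores
#'   strand-symmetric.
#' @return a list of class `consensus_motif`.
#' @export
consensus_motif <- function(motif = "TTCCA", both_strands = TRUE) {
  motif <- normalize_dna(motif, "motif")
  if (nchar(motif) < 2L || grepl("N", motif, fixed = TRUE)) {
    stop("motif must be length >= 2 over A/C/G/T", call. = FALSE)
  }
  structure(list(motif = motif, both_strands = isTRUE(both_strands)),
            class = "consensus_motif")
}

#' Homology of a primer to a consensus motif
#'
#' Counts exact occurrences of the motif (and of its reverse complement
#' when `both_strands`) inside the primer, and the fraction of primer
#' bases covered by the union of the matched footprints.
#'
#' @param primer DNA string, length >= motif length.
#' @param motif a [consensus_motif] (or a plain motif string).
#' @param max_mismatch occurrences with up to this many mismatches also
#'   count (default 0, exact matching).
#' @return named numeric: `match_count`, `coverage`.
#' @export
#' @examples
#' consensus_homology("TTCCATTCCATTCCATTCCTTTCCTTT")  # WYR6: 3 matches
consensus_homology <- function(primer, motif = consensus_motif(),
                               max_mismatch = 0L) {
  if (is.character(motif)) motif <- consensus_motif(motif)
  primer <- normalize_dna(primer, "primer")
  n <- nchar(primer)
  m <- nchar(motif$motif)
  if (n < m) stop("primer shorter than motif", call. = FALSE)
  pats <- motif$motif
  if (motif$both_strands) pats <- unique(c(pats, revcomp(motif$motif)))
  starts <- integer(0)
  count <- 0L
  for (p in pats) {
    sites <- hamming_sites(primer, p, max_mismatch = max_mismatch)
    count <- count + nrow(sites)
    starts <- c(starts, sites$start)
  }
  covered <- logical(n)
  for (s in unique(starts)) covered[s:(s + m - 1L)] <- TRUE
  c(match_count = count, coverage = sum(covered) / n)
}

#' GC fraction of a primer
#'
#' @param primer non-empty DNA string without N.
#' @return fraction of G+C bases, in `[0, 1]`.
#' @export
gc_fraction <- function(primer) {
  primer <- normalize_dna(primer, "primer")
  if (!nzchar(primer)) stop("empty primer", call. = FALSE)
  if (grepl("N", primer, fixed = TRUE)) {
    stop("N in primer: GC fraction undefined", call. = FALSE)
  }
  b <- strsplit(primer, "", fixed = TRUE)[[1L]]
  sum(b %in% c("G", "C")) / length(b)
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C — adequate for ranking short oligos;
#' nearest-neighbour thermodynamics is out of scope.
#'
#' @param primer non-empty DNA string without N.
#' @return Tm in degrees C.
#' @export
tm_wallace <- function(primer) {
  primer <- normalize_dna(primer, "primer")
  if (!nzchar(primer)) stop("empty primer", call. = FALSE)
  if (grepl("N", primer, fixed = TRUE)) {
    stop("N in primer: Tm undefined", call. = FALSE)
  }
  b <- strsplit(primer, "", fixed = TRUE)[[1L]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

#' Enumerate and rank primer candidates on a monomer
#'
#' Scores every substring of each requested length, on both strands, and
#' ranks by ascending consensus coverage, then ascending match count, then
#' ascending |GC - 0.5|, then ascending template offset, then strand ("+"
#' first), then length — a deterministic total order. Optional GC/Tm
#' constraints filter before ranking.
#'
#' @param monomer a [seq_record] (or plain DNA string) of the repeat
#'   monomer.
#' @param length_range integer vector of primer lengths to consider.
#' @param motif a [consensus_motif].
#' @param gc_min,gc_max,tm_min,tm_max optional candidate filters.
#' @param max_candidates truncate the ranked list (default all).
#' @return a data.frame of candidates: `sequence`, `template_start`
#'   (0-based offset of the footprint on the monomer), `strand`, `length`,
#'   `consensus_match_count`, `consensus_coverage`, `gc_fraction`,
#'   `tm_wallace`.
#' @export
enumerate_primers <- function(monomer, length_range = 27L,
                              motif = consensus_motif(),
                              gc_min = 0, gc_max = 1,
                              tm_min = -Inf, tm_max = Inf,
                              max_candidates = Inf) {
  if (is.character(monomer)) monomer <- seq_record("monomer", monomer)
  length_range <- as.integer(length_range)
  if (length(length_range) == 0L) {
    stop("empty length_range", call. = FALSE)
  }
  if (monomer$length < max(length_range)) {
    stop("monomer shorter than requested primer length", call. = FALSE)
  }
  rows <- list()
  for (L in sort(unique(length_range))) {
    starts0 <- 0:(monomer$length - L)
    fwd <- substring(monomer$sequence, starts0 + 1L, starts0 + L)
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") fwd else revcomp(fwd)
      hom <- vapply(seqs, function(s) consensus_homology(s, motif),
                    c(match_count = 0, coverage = 0), USE.NAMES = FALSE)
      has_n <- grepl("N", seqs, fixed = TRUE)
      gc <- ifelse(has_n, NA_real_, vapply(seqs, function(s) {
        b <- strsplit(s, "", fixed = TRUE)[[1L]]
        sum(b %in% c("G", "C")) / length(b)
      }, numeric(1L), USE.NAMES = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs, template_start = starts0, strand = strand,
        length = L,
        consensus_match_count = hom[1L, ],
        consensus_coverage = hom[2L, ],
        gc_fraction = gc,
        tm_wallace = ifelse(has_n, NA_real_, L * 2 + 2 * L * gc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$gc_fraction) &
               out$gc_fraction >= gc_min & out$gc_fraction <= gc_max &
               out$tm_wallace >= tm_min & out$tm_wallace <= tm_max, ,
             drop = FALSE]
  out <- out[order(out$consensus_coverage, out$consensus_match_count,
                   abs(out$gc_fraction - 0.5), out$template_start,
                   out$strand, out$length), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = max_candidates)
}

#' In-silico PCR
#'
#' Locates all binding sites of the forward primer on the plus strand and
#' of the reverse primer (as its reverse complement) on the template, each
#' with at most `max_mismatch` Hamming mismatches (no indels), and reports
#' every forward/reverse pairing whose footprints both lie inside the
#' product and whose product length does not exceed `max_product`.
#'
#' @param template a [seq_record] (or plain DNA string).
#' @param fwd,rev primer sequences (5' to 3', as ordered on a PCR sheet).
#' @param max_mismatch per-primer mismatch allowance (default 0).
#' @param max_product maximum product length in bp (default 5000).
#' @return a data.frame of amplicons, 1-based inclusive template
#'   coordinates, ordered by `start` then `length`: `template_id`, `start`,
#'   `end`, `length`, `fwd_start`, `fwd_mismatches`, `rev_start`,
#'   `rev_mismatches` (the `*_start` columns give each primer footprint's
#'   leftmost template base). No binding sites yields an empty frame.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                         max_product = 5000L) {
  if (is.character(template)) template <- seq_record("template", template)
  fwd <- normalize_dna(fwd, "forward primer")
  rev <- normalize_dna(rev, "reverse primer")
  if (!nzchar(fwd) || !nzchar(rev)) stop("empty primer", call. = FALSE)
  fsites <- hamming_sites(template$sequence, fwd, max_mismatch)
  rsites <- hamming_sites(template$sequence, revcomp(rev), max_mismatch)
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_start = integer(0), fwd_mismatches = integer(0),
                      rev_start = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(fsites) == 0L || nrow(rsites) == 0L) return(empty)
  mf <- nchar(fwd)
  mr <- nchar(rev)
  pairs <- expand.grid(f = seq_len(nrow(fsites)), r = seq_len(nrow(rsites)))
  f0 <- fsites$start[pairs$f]           # fwd 5' end = product start
  r0 <- rsites$start[pairs$r]
  pend <- r0 + mr - 1L                  # rev 5' end = product end
  len <- pend - f0 + 1L
  ok <- f0 <= r0 & (f0 + mf - 1L) <= pend & len <= max_product
  if (!any(ok)) return(empty)
  out <- data.frame(template_id = template$id,
                    start = f0[ok], end = pend[ok], length = len[ok],
                    fwd_start = f0[ok],
                    fwd_mismatches = fsites$mismatches[pairs$f][ok],
                    rev_start = r0[ok],
                    rev_mismatches = rsites$mismatches[pairs$r][ok],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
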