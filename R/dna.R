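#' @title DNA string utilities
#' @description Internal helpers shared across the package. Sequences are
#'   plain R character strings over the alphabet A/C/G/T/N, stored
#'   upper-case. "N" is a legal base but never matches any k-mer, motif or
#'   primer position.
#' @name dna-utils
#' @keywords internal
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a DNA string
#'
#' Upper-cases and validates a sequence. Characters outside A/C/G/T/N are a
#' parse/argument error.
#'
#' @param x character scalar.
#' @param what label used in error messages (e.g. a file line).
#' @return the normalized string.
#' @keywords internal
normalize_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    stop(sprintf("illegal character(s) '%s' in %s", substr(bad, 1L, 10L), what),
         call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("TTCCA")  # "TGGAA"
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Construct a sequence record
#'
#' A minimal container for one named DNA sequence: a list with elements
#' `id`, `sequence` (upper-case A/C/G/T/N) and `length`.
#'
#' @param id character scalar identifier.
#' @param sequence DNA string; normalized upper-case.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence, what = sprintf("record '%s'", id))
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

# All match positions (1-based starts) of `pattern` on `subject` with at most
# max_mismatch Hamming mismatches. No indels. "N" on either side never
# matches. Returns a data.frame(start, mismatches). O(n * m), vectorized
# over the subject.
hamming_sites <- function(subject, pattern, max_mismatch = 0L) {
  n <- nchar(subject)
  m <- nchar(pattern)
  if (m == 0L || n < m) {
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  subj <- strsplit(subject, "", fixed = TRUE)[[1L]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  n_pos <- n - m + 1L
  mm <- integer(n_pos)
  for (j in seq_len(m)) {
    sj <- subj[j:(j + n_pos - 1L)]
    mm <- mm + as.integer(sj != pat[j] | sj == "N" | pat[j] == "N")
  }
  keep <- which(mm <= max_mismatch)
  data.frame(start = keep, mismatches = mm[keep])
}

# All overlapping k-mers of a sequence as a character vector (forward
# strand, in order). K-mers containing N are dropped.
forward_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  km[!grepl("N", km, fixed = TRUE)]
}
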