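#' @title Repeat annotation and clone table I/O
#' @description Readers/writers for the plain-text formats the pipeline
#'   touches: multi-record FASTA, BED3/BED4, the RepeatMasker `.out`
#'   column dialect, and tab-separated BAC clone placement tables.
#'
#'   Internal coordinates are 0-based half-open everywhere. The two
#'   paper-facing conventions are converted only at parse/serialize
#'   boundaries: RepeatMasker query coordinates (1-based inclusive) are
#'   converted on read; BAC clone tables keep 1-based inclusive fields in
#'   the data model because that convention makes every mapped clone row
#'   satisfy insert = end - start + 1.
#' @name repeat-io
NULL

#' Read a FASTA file
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a list of [seq_record] objects, one per header, in file order.
#'   Sequences are normalized upper-case.
#' @details Duplicate ids, sequence data before the first header, and
#'   characters outside A/C/G/T/N are parse errors naming the offending
#'   line. An empty file yields an empty list.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  ids <- character(0)
  cur_id <- NULL
  cur_chunks <- character(0)
  flush <- function() {
    if (is.null(cur_id)) return()
    records[[length(records) + 1L]] <<-
      seq_record(cur_id, paste(cur_chunks, collapse = ""))
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]], which = "right")
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      cur_id <- sub("\\s.*$", "", substring(line, 2L))
      if (!nzchar(cur_id)) {
        stop(sprintf("%s: empty FASTA header at line %d", path, i),
             call. = FALSE)
      }
      if (cur_id %in% ids) {
        stop(sprintf("%s: duplicate id '%s' at line %d", path, cur_id, i),
             call. = FALSE)
      }
      ids <- c(ids, cur_id)
      cur_chunks <- character(0)
    } else {
      if (is.null(cur_id)) {
        stop(sprintf("%s: sequence before first header at line %d (not FASTA?)",
                     path, i), call. = FALSE)
      }
      seq_line <- gsub("\\s", "", line)
      bad <- gsub("[ACGTNacgtn]", "", seq_line)
      if (nzchar(bad)) {
        stop(sprintf("%s: illegal character(s) '%s' at line %d",
                     path, substr(bad, 1L, 10L), i), call. = FALSE)
      }
      cur_chunks <- c(cur_chunks, seq_line)
    }
  }
  flush()
  records
}

#' Write sequence records to FASTA
#'
#' @param records a list of [seq_record] objects.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, open = "wb")  # "wb": byte-identical output across OSes
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    starts <- seq(1L, rec$length, by = width)
    writeLines(substring(rec$sequence, starts,
                         pmin(starts + width - 1L, rec$length)), con)
  }
  invisible(path)
}

#' Construct a repeat-interval table
#'
#' The shared annotation container: a data.frame with columns `chrom`,
#' `start`, `end` (0-based half-open), `strand` ("+"/"-"), `rep_name`,
#' `rep_class`, `rep_family`.
#'
#' @param chrom,start,end,strand,rep_name,rep_class,rep_family vectors,
#'   recycled to a common length.
#' @return a `data.frame` of repeat intervals.
#' @export
repeat_intervals <- function(chrom = character(0), start = integer(0),
                             end = integer(0), strand = "+",
                             rep_name = "repeat", rep_class = "Unknown",
                             rep_family = "") {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      rep_name = character(0), rep_class = character(0),
                      rep_family = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   rep_name = as.character(rep_name),
                   rep_class = as.character(rep_class),
                   rep_family = as.character(rep_family),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    stop("repeat intervals require 0 <= start < end", call. = FALSE)
  }
  if (nrow(df) && any(!nzchar(df$rep_class))) {
    stop("rep_class must be non-empty", call. = FALSE)
  }
  df
}

#' Parse a RepeatMasker .out file
#'
#' Tolerates the usual two header lines (plus a blank line); leading lines
#' whose first field is not numeric are skipped. Query coordinates are
#' 1-based inclusive in the file and converted to the internal 0-based
#' half-open convention; strand "C" maps to "-"; a combined
#' "class/family" column (e.g. "SINE/Alu") is split.
#'
#' @param path path to a `.out`-dialect file.
#' @return a repeat-interval data.frame (see [repeat_intervals]).
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  n_skipped <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(fields) == 0L || !nzchar(fields[[1L]])) next
    if (is.na(suppressWarnings(as.numeric(fields[[1L]])))) {
      # header lines: only tolerated before any data row
      if (sum(!vapply(out, is.null, logical(1))) == 0L && n_skipped < 3L) {
        n_skipped <- n_skipped + 1L
        next
      }
      stop(sprintf("%s: unparseable row at line %d", path, i), call. = FALSE)
    }
    if (length(fields) < 11L) {
      stop(sprintf("%s: missing columns at line %d", path, i), call. = FALSE)
    }
    qstart <- suppressWarnings(as.numeric(fields[[6L]]))
    qend <- suppressWarnings(as.numeric(fields[[7L]]))
    if (is.na(qstart) || is.na(qend)) {
      stop(sprintf("%s: non-numeric coordinates at line %d", path, i),
           call. = FALSE)
    }
    strand <- if (fields[[9L]] == "C") "-" else fields[[9L]]
    cf <- strsplit(fields[[11L]], "/", fixed = TRUE)[[1L]]
    out[[i]] <- data.frame(
      chrom = fields[[5L]],
      start = qstart - 1,   # 1-based inclusive -> 0-based half-open
      end = qend,
      strand = strand,
      rep_name = fields[[10L]],
      rep_class = cf[[1L]],
      rep_family = if (length(cf) > 1L) cf[[2L]] else "",
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(repeat_intervals())
  do.call(rbind, out)
}

#' Parse a BED3/BED4 file
#'
#' BED is already 0-based half-open; no coordinate conversion. The optional
#' name column is used as both `rep_class` and `rep_name`.
#'
#' @param path path to a BED file.
#' @return a repeat-interval data.frame.
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(repeat_intervals())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("%s: fewer than 3 columns at line %d", path, i),
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(fields[[2L]]))
    e <- suppressWarnings(as.numeric(fields[[3L]]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s: non-numeric coordinates at line %d", path, i),
           call. = FALSE)
    }
    if (s >= e) {
      stop(sprintf("%s: start >= end at line %d", path, i), call. = FALSE)
    }
    name <- if (length(fields) >= 4L) fields[[4L]] else "region"
    out[[i]] <- data.frame(chrom = fields[[1L]], start = s, end = e,
                           strand = "+", rep_name = name, rep_class = name,
                           rep_family = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write intervals to BED4
#'
#' Writes `chrom`, `start`, `end` and `rep_class` as the name column, so
#' that `parse_bed(write_bed(x))` round-trips (chrom, start, end, name).
#'
#' @param regions a repeat-interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(regions)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom,
                       as.integer(regions$start), as.integer(regions$end),
                       regions$rep_class), con)
  }
  invisible(path)
}

#' Parse a BAC clone placement table
#'
#' Tab-separated with a header row; columns: name, chromosome, band, start,
#' end, insert size, end-sequence accessions. Numeric fields may carry
#' comma thousands-separators (stripped). Coordinate fields may be the
#' literal "multiple", flagging a multi-mapping clone with absent
#' coordinates. Coordinates are kept in the table's own 1-based inclusive
#' convention (see [clone_span_bp]).
#'
#' @param path path to the TSV.
#' @return a data.frame with columns `name`, `chrom`, `band`, `start`,
#'   `end` (1-based inclusive, `NA` when multi-mapping), `insert_size`,
#'   `accessions` (comma-joined), `multi_mapping` (logical).
#' @export
parse_clone_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) return(empty_clone_table())
  parse_coord <- function(x, i) {
    if (tolower(trimws(x)) == "multiple") return(NA_real_)
    v <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
    if (is.na(v)) {
      stop(sprintf("%s: non-numeric coordinate '%s' at line %d", path, x, i),
           call. = FALSE)
    }
    v
  }
  out <- vector("list", length(lines) - 1L)
  for (i in 2L:length(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 7L) {
      stop(sprintf("%s: fewer than 7 columns at line %d", path, i),
           call. = FALSE)
    }
    s <- parse_coord(fields[[4L]], i)
    e <- parse_coord(fields[[5L]], i)
    ins <- suppressWarnings(as.numeric(gsub(",", "", fields[[6L]],
                                            fixed = TRUE)))
    if (is.na(ins)) {
      stop(sprintf("%s: non-numeric insert size at line %d", path, i),
           call. = FALSE)
    }
    multi <- is.na(s) || is.na(e)
    if (!multi && s > e) {
      stop(sprintf("%s: start > end at line %d", path, i), call. = FALSE)
    }
    acc <- paste(trimws(strsplit(fields[[7L]], ",", fixed = TRUE)[[1L]]),
                 collapse = ",")
    out[[i - 1L]] <- data.frame(
      name = trimws(fields[[1L]]), chrom = trimws(fields[[2L]]),
      band = trimws(fields[[3L]]),
      start = if (multi) NA_real_ else s, end = if (multi) NA_real_ else e,
      insert_size = ins, accessions = acc, multi_mapping = multi,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_clone_table <- function() {
  data.frame(name = character(0), chrom = character(0), band = character(0),
             start = numeric(0), end = numeric(0), insert_size = numeric(0),
             accessions = character(0), multi_mapping = logical(0),
             stringsAsFactors = FALSE)
}

#' Coordinate convention converters
#'
#' `to_internal()` maps 1-based inclusive (start, end) to 0-based half-open;
#' `to_paper()` is its inverse. Round-tripping is the identity.
#'
#' @param start,end coordinate vectors.
#' @return a list with converted `start` and `end`.
#' @export
to_internal <- function(start, end) list(start = start - 1, end = end)

#' @rdname to_internal
#' @export
to_paper <- function(start, end) list(start = start + 1, end = end)
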