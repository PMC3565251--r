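#' @title Satellite target region discovery
#' @description Sliding-window scan of a chromosome's repeat annotation for
#'   regions densely covered by tandem satellite DNA but free of
#'   interspersed (transposon-derived, hence non chromosome-specific)
#'   elements. Qualifying windows are merged into candidate target regions
#'   from which FISH probe clones can be picked.
#' @name target-discovery
NULL

#' Scan configuration
#'
#' @param window window size in bp.
#' @param step window step in bp; `0 < step <= window`.
#' @param min_satellite_fraction minimum fraction of window bases covered
#'   by satellite-class repeats.
#' @param max_interspersed_fraction maximum fraction covered by
#'   interspersed-class repeats. The default 0 takes "free of interspersed
#'   repeats" literally.
#' @param satellite_classes repeat classes counted as satellite.
#' @param interspersed_classes repeat classes that disqualify a window.
#'   Simple_repeat and Low_complexity belong to neither set by default.
#' @param min_region_length merged regions shorter than this are dropped.
#' @param single_family if `TRUE`, additionally require that one satellite
#'   `rep_name` accounts for all satellite coverage in a merged region.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(window = 10000L, step = 1000L,
                        min_satellite_fraction = 0.8,
                        max_interspersed_fraction = 0.0,
                        satellite_classes = "Satellite",
                        interspersed_classes = c("SINE", "LINE", "LTR",
                                                 "DNA", "Retroposon"),
                        min_region_length = 20000L,
                        single_family = FALSE) {
  stopifnot(step > 0, step <= window,
            min_satellite_fraction >= 0, min_satellite_fraction <= 1,
            max_interspersed_fraction >= 0, max_interspersed_fraction <= 1)
  if (length(intersect(satellite_classes, interspersed_classes)) > 0L) {
    stop("satellite_classes and interspersed_classes must be disjoint",
         call. = FALSE)
  }
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_satellite_fraction = min_satellite_fraction,
                 max_interspersed_fraction = max_interspersed_fraction,
                 satellite_classes = satellite_classes,
                 interspersed_classes = interspersed_classes,
                 min_region_length = as.integer(min_region_length),
                 single_family = isTRUE(single_family)),
            class = "scan_config")
}

# Union-of-overlaps covered bases of `intervals` clipped to [start, end),
# internal convention. Overlapping annotations are not double-counted.
covered_bases <- function(starts, ends, start, end) {
  if (length(starts) == 0L) return(0)
  s <- pmax(starts, start)
  e <- pmin(ends, end)
  keep <- s < e
  if (!any(keep)) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1, end = e[keep]))
  sum(IRanges::width(r))
}

#' Class-set coverage fractions of one window
#'
#' Fractions are union-of-overlaps base coverage by the satellite and
#' interspersed class sets, clipped to the window, divided by the window
#' length.
#'
#' @param intervals repeat-interval data.frame (internal coordinates).
#' @param chrom chromosome name; rows on other chromosomes are ignored.
#' @param start,end window, 0-based half-open; `end > start` required.
#' @param config a [scan_config].
#' @return named numeric: `satellite_fraction`, `interspersed_fraction`.
#' @export
window_composition <- function(intervals, chrom, start, end,
                               config = scan_config()) {
  if (end <= start) stop("window end must exceed start", call. = FALSE)
  ivl <- intervals[intervals$chrom == chrom, , drop = FALSE]
  sat <- ivl$rep_class %in% config$satellite_classes
  int <- ivl$rep_class %in% config$interspersed_classes
  w <- end - start
  c(satellite_fraction =
      covered_bases(ivl$start[sat], ivl$end[sat], start, end) / w,
    interspersed_fraction =
      covered_bases(ivl$start[int], ivl$end[int], start, end) / w)
}

#' Scan a chromosome for candidate satellite target regions
#'
#' Slides a window along the chromosome, keeps windows whose satellite
#' coverage reaches `min_satellite_fraction` while interspersed coverage
#' stays at or below `max_interspersed_fraction`, merges overlapping or
#' exactly abutting qualifying windows, drops merged regions shorter than
#' `min_region_length`, and recomputes both fractions over each merged
#' span (regions whose recomputed fractions fail the thresholds are
#' dropped, so the reported composition always honours the criterion).
#'
#' @param intervals repeat annotation for one chromosome (internal
#'   coordinates).
#' @param chrom_length chromosome length in bp.
#' @param config a [scan_config].
#' @param chrom chromosome name; defaults to the single name present in
#'   `intervals`.
#' @return a data.frame of candidate regions with columns `chrom`, `start`,
#'   `end` (0-based half-open), `length`, `satellite_fraction`,
#'   `interspersed_fraction`, `dominant_rep_name`, `n_windows`; sorted by
#'   start, non-overlapping.
#' @export
scan_candidate_regions <- function(intervals, chrom_length,
                                   config = scan_config(),
                                   chrom = NULL) {
  if (is.null(chrom)) {
    chroms <- unique(intervals$chrom)
    if (length(chroms) > 1L) {
      stop("intervals span several chromosomes; pass `chrom`", call. = FALSE)
    }
    chrom <- if (length(chroms)) chroms else NA_character_
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      satellite_fraction = numeric(0),
                      interspersed_fraction = numeric(0),
                      dominant_rep_name = character(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (config$window > chrom_length) {
    warning("window exceeds chromosome length; no windows scanned",
            call. = FALSE)
    return(empty)
  }
  ivl <- intervals[intervals$chrom %in% chrom, , drop = FALSE]
  if (nrow(ivl) == 0L) return(empty)

  win_starts <- seq.int(0L, chrom_length - config$window, by = config$step)
  windows <- IRanges::IRanges(start = win_starts + 1,
                              width = config$window)
  class_cov <- function(sel) {
    # per-window covered bases by one class set, via overlap intersection
    cov <- numeric(length(win_starts))
    if (!any(sel)) return(cov)
    r <- IRanges::reduce(IRanges::IRanges(start = ivl$start[sel] + 1,
                                          end = ivl$end[sel]))
    hits <- IRanges::findOverlaps(windows, r)
    if (length(hits) == 0L) return(cov)
    w <- IRanges::width(IRanges::pintersect(
      windows[S4Vectors::queryHits(hits)], r[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
    cov
  }
  sat_cov <- class_cov(ivl$rep_class %in% config$satellite_classes)
  int_cov <- class_cov(ivl$rep_class %in% config$interspersed_classes)
  ok <- sat_cov / config$window >= config$min_satellite_fraction &
    int_cov / config$window <= config$max_interspersed_fraction
  if (!any(ok)) return(empty)

  merged <- IRanges::reduce(windows[ok])  # joins overlapping/abutting only
  n_win <- IRanges::countOverlaps(merged, windows[ok])
  out <- data.frame(chrom = chrom,
                    start = IRanges::start(merged) - 1,
                    end = as.numeric(IRanges::end(merged)),
                    n_windows = n_win, stringsAsFactors = FALSE)
  out <- out[out$end - out$start >= config$min_region_length, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)

  comp <- t(vapply(seq_len(nrow(out)), function(i) {
    window_composition(ivl, chrom, out$start[i], out$end[i], config)
  }, numeric(2L)))
  out$satellite_fraction <- comp[, "satellite_fraction"]
  out$interspersed_fraction <- comp[, "interspersed_fraction"]
  out$length <- out$end - out$start
  out$dominant_rep_name <- vapply(seq_len(nrow(out)), function(i) {
    sat <- ivl[ivl$rep_class %in% config$satellite_classes, , drop = FALSE]
    if (nrow(sat) == 0L) return(NA_character_)
    cov <- vapply(split(seq_len(nrow(sat)), sat$rep_name), function(j) {
      covered_bases(sat$start[j], sat$end[j], out$start[i], out$end[i])
    }, numeric(1L))
    cov <- cov[cov > 0]
    if (length(cov) == 0L) return(NA_character_)
    names(cov)[order(-cov, names(cov))][1L]
  }, character(1L))
  keep <- out$satellite_fraction >= config$min_satellite_fraction &
    out$interspersed_fraction <= config$max_interspersed_fraction
  if (config$single_family) {
    keep <- keep & vapply(seq_len(nrow(out)), function(i) {
      sat <- ivl[ivl$rep_class %in% config$satellite_classes, , drop = FALSE]
      fam_cov <- vapply(split(seq_len(nrow(sat)), sat$rep_name), function(j) {
        covered_bases(sat$start[j], sat$end[j], out$start[i], out$end[i])
      }, numeric(1L))
      sum(fam_cov > 0) <= 1L
    }, logical(1L))
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start),
             c("chrom", "start", "end", "length", "satellite_fraction",
               "interspersed_fraction", "dominant_rep_name", "n_windows")]
  rownames(out) <- NULL
  out
}

#' Rank candidate regions
#'
#' Stable sort by satellite fraction (descending), then length
#' (descending), then start (ascending) — a deterministic total order.
#'
#' @param regions a candidate-region data.frame.
#' @return the same data.frame, reordered.
#' @export
rank_regions <- function(regions) {
  if (nrow(regions) == 0L) return(regions)
  out <- regions[order(-regions$satellite_fraction,
                       -(regions$end - regions$start),
                       regions$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate-region report
#'
#' Emits BED4 (name = dominant repeat) and, optionally, a TSV with the
#' composition fractions. Machine-readable output carries no thousands
#' separators.
#'
#' @param regions candidate-region data.frame.
#' @param bed_path BED4 output path.
#' @param tsv_path optional TSV report path.
#' @return `bed_path`, invisibly.
#' @export
write_region_report <- function(regions, bed_path, tsv_path = NULL) {
  bed <- regions
  bed$rep_class <- ifelse(is.na(regions$dominant_rep_name), "region",
                          regions$dominant_rep_name)
  write_bed(bed, bed_path)
  if (!is.null(tsv_path)) {
    utils::write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}
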