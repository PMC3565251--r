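#' @title BAC clone selection and consistency checks
#' @description Pick BAC clones suitable as FISH probes for a candidate
#'   region, and cross-check a clone table's printed insert sizes against
#'   its mapped end coordinates. Clone tables are 1-based inclusive (the
#'   convention under which every mapped row satisfies
#'   insert = end - start + 1); candidate regions use the internal 0-based
#'   half-open convention, and the conversion happens inside
#'   [select_clones].
#' @name clone-selection
NULL

#' Clone selection policy
#'
#' @param mode `"contained"` keeps clones lying entirely within the region
#'   (the default: probes are chosen *within* the satellite block);
#'   `"overlap"` keeps clones whose overlap with the region, as a fraction
#'   of the clone span, reaches `min_overlap_fraction`.
#' @param min_overlap_fraction used in overlap mode, in `[0, 1]`.
#' @param allow_multimapping if `TRUE`, multi-mapping clones are reported
#'   separately as dispersed-target probe candidates (attribute
#'   `"dispersed"` on the result); they are never selected as unique
#'   probes.
#' @return a list of class `selection_policy`.
#' @export
selection_policy <- function(mode = c("contained", "overlap"),
                             min_overlap_fraction = 0.5,
                             allow_multimapping = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  structure(list(mode = mode,
                 min_overlap_fraction = min_overlap_fraction,
                 allow_multimapping = isTRUE(allow_multimapping)),
            class = "selection_policy")
}

strip_chr <- function(x) sub("^chr", "", x)

#' Select clones for a candidate region
#'
#' @param clones clone table from [parse_clone_table] (1-based inclusive).
#' @param region a list or one-row data.frame with `chrom`, `start`, `end`
#'   in the internal 0-based half-open convention (e.g. one row of
#'   [scan_candidate_regions] output, or [region_from_paper_coords]).
#' @param policy a [selection_policy].
#' @return the selected rows of `clones`. When
#'   `policy$allow_multimapping`, multi-mapping clones on the region's
#'   chromosome are attached as `attr(result, "dispersed")`.
#' @details Chromosome names are matched exactly after stripping an
#'   optional `"chr"` prefix. A region chromosome absent from the clone
#'   table yields an empty selection with a warning.
#' @export
select_clones <- function(clones, region, policy = selection_policy()) {
  rchrom <- strip_chr(region$chrom)
  on_chrom <- strip_chr(clones$chrom) == rchrom
  if (!any(on_chrom)) {
    warning(sprintf("chromosome '%s' absent from clone table", region$chrom),
            call. = FALSE)
    sel <- clones[integer(0), , drop = FALSE]
    if (policy$allow_multimapping) attr(sel, "dispersed") <-
        clones[integer(0), , drop = FALSE]
    return(sel)
  }
  cand <- clones[on_chrom, , drop = FALSE]
  dispersed <- cand[cand$multi_mapping, , drop = FALSE]
  cand <- cand[!cand$multi_mapping, , drop = FALSE]
  # convert clone coordinates to internal convention for the comparison
  cs <- cand$start - 1
  ce <- cand$end
  keep <- if (policy$mode == "contained") {
    cs >= region$start & ce <= region$end
  } else {
    ov <- pmax(0, pmin(ce, region$end) - pmax(cs, region$start))
    span <- ce - cs
    ov / span >= policy$min_overlap_fraction
  }
  sel <- cand[keep, , drop = FALSE]
  rownames(sel) <- NULL
  if (policy$allow_multimapping) {
    rownames(dispersed) <- NULL
    attr(sel, "dispersed") <- dispersed
  }
  sel
}

#' Region from 1-based inclusive coordinates
#'
#' Convenience constructor for regions quoted in browser/paper convention,
#' converting to the internal 0-based half-open convention.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @return a list with `chrom`, `start`, `end` (internal convention).
#' @export
region_from_paper_coords <- function(chrom, start, end) {
  stopifnot(start <= end)
  list(chrom = chrom, start = start - 1, end = end)
}

#' Span of a mapped clone in bp
#'
#' Under the clone table's 1-based inclusive convention the span is
#' `end - start + 1`, which equals the printed insert size for every
#' internally consistent row.
#'
#' @param start,end 1-based inclusive coordinates; `start <= end` required.
#' @return span in bp.
#' @export
#' @examples
#' clone_span_bp(46385822, 46412445)  # 26624
clone_span_bp <- function(start, end) {
  if (any(start > end)) stop("start must not exceed end", call. = FALSE)
  end - start + 1
}

#' Check clone table internal consistency
#'
#' One report row per clone: mapped clones compare span (end - start + 1)
#' with the reported insert size; multi-mapping clones get an
#' not-applicable report (`NA` span, `NA` consistent).
#'
#' @param clones clone table from [parse_clone_table].
#' @param tolerance maximum `|span - insert|` still counted consistent.
#' @return a data.frame with columns `name`, `span_bp`, `reported_insert`,
#'   `delta`, `consistent`.
#' @export
check_clone_consistency <- function(clones, tolerance = 0) {
  span <- ifelse(clones$multi_mapping, NA_real_,
                 clones$end - clones$start + 1)
  delta <- span - clones$insert_size
  data.frame(name = clones$name,
             span_bp = span,
             reported_insert = clones$insert_size,
             delta = delta,
             consistent = ifelse(is.na(span), NA, abs(delta) <= tolerance),
             stringsAsFactors = FALSE)
}
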