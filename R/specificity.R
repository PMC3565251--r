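#' @title k-mer cross-chromosome specificity profiling
#' @description A deterministic, desk-scale surrogate for an interactive
#'   BLASTn screen: decompose a candidate probe into overlapping k-mers,
#'   count where those k-mers occur across a genome, and classify the
#'   probe as chromosome-specific, dispersed, or at off-target risk. The
#'   mapping from BLAST word/E-value sensitivity settings to a k value is
#'   heuristic, not an equivalence.
#' @name specificity
NULL

#' Specificity screen configuration
#'
#' @param k k-mer length; `4 <= k <= probe length` is enforced at use.
#' @param count_both_strands if `TRUE` (default), k-mers are canonicalized
#'   (lexicographic minimum of the k-mer and its reverse complement), so
#'   hits on either strand count.
#' @param pseudocount added to every chromosome's hit count before the
#'   target fraction is computed (default 0).
#' @return a list of class `specificity_config`.
#' @export
specificity_config <- function(k = 16L, count_both_strands = TRUE,
                               pseudocount = 0) {
  stopifnot(k >= 4L, pseudocount >= 0)
  structure(list(k = as.integer(k),
                 count_both_strands = isTRUE(count_both_strands),
                 pseudocount = pseudocount),
            class = "specificity_config")
}

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Overlapping k-mers of a probe
#'
#' All overlapping k-mers of the probe in template order (a multiset:
#' repeated k-mers appear repeatedly). K-mers containing N are skipped.
#' With `count_both_strands` each k-mer is canonicalized.
#'
#' @param probe DNA string, length >= k.
#' @param config a [specificity_config].
#' @return character vector of (canonical) k-mers.
#' @export
probe_kmers <- function(probe, config = specificity_config()) {
  probe <- normalize_dna(probe, "probe")
  if (nchar(probe) < config$k) {
    stop("probe shorter than k", call. = FALSE)
  }
  km <- forward_kmers(probe, config$k)
  if (config$count_both_strands) km <- canonical_kmer(km)
  km
}

#' Genome-wide hit profile of a probe
#'
#' For each chromosome, counts the positions whose k-mer belongs to the
#' probe's k-mer set (distinct k-mers; overlapping genome occurrences all
#' count, because satellite targets are tandem and collapsing overlaps
#' would understate copy number).
#'
#' @param probe DNA string (or [seq_record]).
#' @param genome list of [seq_record] chromosomes.
#' @param target_chrom name of the intended target chromosome.
#' @param config a [specificity_config].
#' @return a list of class `specificity_report`: `probe_id`,
#'   `per_chrom_hits` (named numeric), `total_hits`, `target_chrom`,
#'   `target_fraction` (`NA` when there are no hits), `no_hits` flag.
#' @export
genome_hit_profile <- function(probe, genome, target_chrom,
                               config = specificity_config()) {
  if (inherits(probe, "seq_record")) {
    probe_id <- probe$id
    probe <- probe$sequence
  } else {
    probe_id <- "probe"
  }
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  kms <- unique(probe_kmers(probe, config))
  # expand to both literal orientations so plain forward genome k-mers can
  # be matched without canonicalizing millions of strings
  keys <- if (config$count_both_strands) unique(c(kms, revcomp(kms))) else kms
  hits <- vapply(genome, function(chrom) {
    sum(forward_kmers(chrom$sequence, config$k) %in% keys)
  }, numeric(1L))
  names(hits) <- vapply(genome, `[[`, character(1L), "id")
  total <- sum(hits)
  structure(list(probe_id = probe_id,
                 per_chrom_hits = hits,
                 total_hits = total,
                 target_chrom = target_chrom,
                 target_fraction = if (total > 0) {
                   (hits[[target_chrom]] + config$pseudocount) /
                     (total + config$pseudocount * length(hits))
                 } else NA_real_,
                 no_hits = total == 0),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report> %s -> target %s\n", x$probe_id,
              x$target_chrom))
  if (x$no_hits) {
    cat("  no hits\n")
  } else {
    cat(sprintf("  total hits %d, target fraction %.4f\n",
                as.integer(x$total_hits), x$target_fraction))
    for (nm in names(x$per_chrom_hits)) {
      cat(sprintf("  %-12s %d\n", nm, as.integer(x$per_chrom_hits[[nm]])))
    }
  }
  invisible(x)
}

#' Classify a probe from its hit profile
#'
#' `chromosome_specific` when the target fraction and target hit count
#' both clear their thresholds (at least `min_target_fraction` /
#' `min_target_hits`); `dispersed` when at least two chromosomes each
#' carry strictly more than `min_target_hits` hits (the behaviour of a
#' repeat probe binding many sites genome-wide); `off_target_risk`
#' otherwise; `no_hits` when the profile is empty.
#'
#' @param report a `specificity_report`.
#' @param min_target_fraction minimum hits(target)/total for specificity.
#' @param min_target_hits minimum absolute hit count per chromosome.
#' @return one of `"chromosome_specific"`, `"dispersed"`,
#'   `"off_target_risk"`, `"no_hits"`.
#' @export
classify_probe <- function(report, min_target_fraction = 0.95,
                           min_target_hits = 10) {
  if (isTRUE(report$no_hits)) return("no_hits")
  target_hits <- report$per_chrom_hits[[report$target_chrom]]
  if (!is.na(report$target_fraction) &&
      report$target_fraction >= min_target_fraction &&
      target_hits >= min_target_hits) {
    return("chromosome_specific")
  }
  if (sum(report$per_chrom_hits > min_target_hits) >= 2L) {
    return("dispersed")
  }
  "off_target_risk"
}

#' Write a specificity report as TSV
#'
#' @param report a `specificity_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specificity_report <- function(report, path) {
  df <- data.frame(probe_id = report$probe_id,
                   chrom = names(report$per_chrom_hits),
                   hits = as.numeric(report$per_chrom_hits),
                   target = names(report$per_chrom_hits) ==
                     report$target_chrom,
                   target_fraction = report$target_fraction,
                   classification = classify_probe(report),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
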