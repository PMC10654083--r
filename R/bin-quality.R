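#' Quality thresholds for contig trimming and bin selection
#'
#' Default values follow common MAG-curation practice: assemblies trimmed to
#' contigs longer than 1,000 bp, binning restricted to contigs of at least
#' 2,500 bp with a 200 kb bin length floor, and high-quality selection at
#' more than 90% completeness and less than 5% redundancy. The completeness
#' and redundancy inequalities are strict ("more than" / "less than"), so
#' boundary values 90 and 5 are excluded; pass different thresholds for
#' inclusive conventions.
#'
#' @param min_completeness Minimum completeness percent (exclusive).
#' @param max_redundancy Maximum redundancy percent (exclusive).
#' @param min_contig_len_assembly Assembly-level contig trim length, bp
#'   (exclusive: contigs must be longer).
#' @param min_contig_len_binning Binning-level minimum contig length, bp.
#' @param min_bin_len Minimum total bin length, bp (inclusive).
#' @return An object of class \code{quality_thresholds}.
#' @export
quality_thresholds <- function(min_completeness = 90, max_redundancy = 5,
                               min_contig_len_assembly = 1000,
                               min_contig_len_binning = 2500,
                               min_bin_len = 200000) {
  vals <- c(min_completeness, max_redundancy, min_contig_len_assembly,
            min_contig_len_binning, min_bin_len)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all quality thresholds must be finite and non-negative")
  }
  if (min_contig_len_binning < min_contig_len_assembly) {
    stop("min_contig_len_binning must be >= min_contig_len_assembly")
  }
  structure(list(min_completeness = min_completeness,
                 max_redundancy = max_redundancy,
                 min_contig_len_assembly = min_contig_len_assembly,
                 min_contig_len_binning = min_contig_len_binning,
                 min_bin_len = min_bin_len),
            class = "quality_thresholds")
}

#' Trim contigs below a length cutoff
#'
#' Keeps contigs strictly longer than \code{min_len}, preserving input order.
#'
#' @param contigs A data.frame with at least a \code{length} column (bp).
#' @param min_len Length cutoff, bp; contigs of exactly \code{min_len} are
#'   removed.
#' @return The filtered data.frame.
#' @export
trim_contigs <- function(contigs, min_len = 1000) {
  stopifnot("length" %in% names(contigs), min_len >= 0)
  contigs[contigs$length > min_len, , drop = FALSE]
}

#' Select high-quality genome bins
#'
#' Keeps bins with completeness strictly above \code{min_completeness},
#' redundancy strictly below \code{max_redundancy}, and total length of at
#' least \code{min_bin_len}. Counts of bins failing each criterion are
#' attached as the \code{"criteria_counts"} attribute.
#'
#' @param bins Bin QC data.frame with columns \code{bin_id},
#'   \code{completeness}, \code{redundancy}, \code{total_length}.
#' @param th A \code{\link{quality_thresholds}} object.
#' @return Subset of \code{bins} passing all criteria.
#' @export
select_high_quality <- function(bins, th = quality_thresholds()) {
  req <- c("bin_id", "completeness", "redundancy", "total_length")
  stopifnot(all(req %in% names(bins)))
  na_row <- which(is.na(bins$completeness) | is.na(bins$redundancy) |
                    is.na(bins$total_length))
  if (length(na_row) > 0L) {
    stop("missing QC value for bin '", bins$bin_id[na_row[1L]], "'")
  }
  pass_comp <- bins$completeness > th$min_completeness
  pass_red <- bins$redundancy < th$max_redundancy
  pass_len <- bins$total_length >= th$min_bin_len
  keep <- pass_comp & pass_red & pass_len
  out <- bins[keep, , drop = FALSE]
  attr(out, "criteria_counts") <- c(
    n_input = nrow(bins),
    n_kept = sum(keep),
    fail_completeness = sum(!pass_comp),
    fail_redundancy = sum(!pass_red),
    fail_min_length = sum(!pass_len)
  )
  out
}
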