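#' Sharing and host-specificity statistics for selected bins
#'
#' From a presence matrix, bin provenance (which sample each bin was
#' reconstructed from) and sample metadata, tallies how bins are distributed
#' across the host hierarchy:
#'
#' \itemize{
#'   \item per-sample detected-bin counts and their mean;
#'   \item per-bin counts of fecal samples, host species and host orders in
#'     which the bin is detected, and their means;
#'   \item bins "shared" beyond their source sample (detected in at least
#'     one fecal sample other than the one they were reconstructed from);
#'   \item bins detected in exactly one sample, one species, one order, and
#'     their multi-sample/species/order complements;
#'   \item bins never detected in any fecal sample.
#' }
#'
#' Soil samples never count toward host rollups (see
#' \code{\link{environmental_overlap}} for the soil check). Species- and
#' order-level presence requires at least one detected fecal sample of that
#' species/order. Means are computed over all bins, undetected bins
#' contributing zero; set \code{include_undetected = FALSE} to drop them
#' from the means only.
#'
#' @param pm A \code{\link{call_presence}} result.
#' @param bins Bin data.frame with \code{bin_id} and \code{source_sample}.
#' @param meta Sample metadata data.frame (see
#'   \code{\link{read_sample_metadata}}).
#' @param include_undetected Include never-detected bins in means (default
#'   TRUE).
#' @return Object of class \code{sharing_report}; a list of the tallies
#'   above plus a \code{per_bin} data.frame and the species-level presence
#'   matrix used for overlays.
#' @export
summarize_sharing <- function(pm, bins, meta, include_undetected = TRUE) {
  stopifnot(inherits(pm, "presence_matrix"))
  present <- pm$present
  unknown <- setdiff(colnames(present), meta$sample_id)
  if (length(unknown) > 0L) {
    stop("sample '", unknown[1L], "' in presence matrix is absent from metadata")
  }
  bins <- bins[match(rownames(present), bins$bin_id), , drop = FALSE]
  if (anyNA(bins$bin_id)) stop("presence matrix contains bins without provenance")
  bad_src <- setdiff(bins$source_sample, colnames(present))
  if (length(bad_src) > 0L) {
    stop("source sample '", bad_src[1L], "' not in the presence matrix")
  }

  meta_f <- meta[match(colnames(present), meta$sample_id), , drop = FALSE]
  fecal <- meta_f$sample_type == "fecal"
  fp <- present[, fecal, drop = FALSE]
  species <- meta_f$host_species[fecal]
  orders <- meta_f$host_order[fecal]

  n_bins <- nrow(fp)
  samples_per_bin <- rowSums(fp)
  per_sample_detected <- colSums(fp)

  # bins x species / bins x orders presence: any detected fecal sample of
  # that species/order
  agg_presence <- function(groups) {
    g <- unique(groups)
    m <- vapply(g, function(x) {
      rowSums(fp[, groups == x, drop = FALSE]) > 0
    }, logical(n_bins))
    matrix(m, nrow = n_bins, dimnames = list(rownames(fp), g))
  }
  sp_pres <- agg_presence(species)
  or_pres <- agg_presence(orders)
  species_per_bin <- rowSums(sp_pres)
  orders_per_bin <- rowSums(or_pres)

  src_idx <- match(bins$source_sample, colnames(present))
  detected_elsewhere <- vapply(seq_len(n_bins), function(i) {
    cols <- which(fecal)
    cols <- cols[cols != src_idx[i]]
    any(present[i, cols])
  }, logical(1))

  undetected <- samples_per_bin == 0
  per_bin <- data.frame(
    bin_id = rownames(fp),
    source_sample = bins$source_sample,
    samples_per_bin = as.integer(samples_per_bin),
    species_per_bin = as.integer(species_per_bin),
    orders_per_bin = as.integer(orders_per_bin),
    shared_beyond_source = detected_elsewhere,
    single_sample = samples_per_bin == 1,
    undetected = undetected,
    stringsAsFactors = FALSE
  )

  mean_over <- function(x) {
    if (include_undetected) mean(x) else mean(x[!undetected])
  }

  structure(list(
    n_bins = n_bins,
    n_undetected = sum(undetected),
    per_sample_detected = per_sample_detected,
    mean_detected_per_sample = mean(per_sample_detected),
    samples_per_bin = setNames(as.integer(samples_per_bin), rownames(fp)),
    mean_samples_per_bin = mean_over(samples_per_bin),
    n_shared_beyond_source = sum(detected_elsewhere),
    n_single_sample = sum(samples_per_bin == 1),
    species_per_bin = setNames(as.integer(species_per_bin), rownames(fp)),
    mean_species_per_bin = mean_over(species_per_bin),
    n_species_specific = sum(species_per_bin == 1),
    n_multi_species = sum(species_per_bin >= 2),
    orders_per_bin = setNames(as.integer(orders_per_bin), rownames(fp)),
    mean_orders_per_bin = mean_over(orders_per_bin),
    n_single_order = sum(orders_per_bin == 1),
    n_multi_order = sum(orders_per_bin >= 2),
    per_bin = per_bin,
    species_presence = sp_pres,
    include_undetected = include_undetected,
    threshold = pm$threshold,
    strict = pm$strict
  ), class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat("sharing_report over", x$n_bins, "bins (detection",
      if (x$strict) ">" else ">=", paste0(x$threshold, "):\n"))
  cat("  undetected in any fecal sample:", x$n_undetected, "\n")
  cat("  mean bins detected per sample:",
      sprintf("%.2f", x$mean_detected_per_sample), "\n")
  cat("  shared beyond source sample:", x$n_shared_beyond_source,
      "| single-sample:", x$n_single_sample, "\n")
  cat("  mean samples per bin:", sprintf("%.2f", x$mean_samples_per_bin),
      "| mean species per bin:", sprintf("%.2f", x$mean_species_per_bin),
      "| mean orders per bin:", sprintf("%.2f", x$mean_orders_per_bin), "\n")
  cat("  species-specific:", x$n_species_specific, "| multi-species:",
      x$n_multi_species, "\n")
  cat("  single-order:", x$n_single_order, "| multi-order:",
      x$n_multi_order, "\n")
  if (!is.null(x$chitinolytic_overlay)) {
    ov <- x$chitinolytic_overlay$counts
    cat("  chitinolytic overlay (", x$chitinolytic_overlay$n_chitinolytic,
        " chitinolytic bins):\n", sep = "")
    print(ov)
  }
  invisible(x)
}

#' Bins detected in environmental (soil) samples
#'
#' Returns the bins of \code{bin_subset} (default: all bins in the matrix)
#' present in at least one soil sample under the matrix's threshold rule.
#' If the metadata contains no soil samples an empty set is returned with a
#' warning.
#'
#' @param pm A \code{\link{call_presence}} result.
#' @param meta Sample metadata data.frame.
#' @param bin_subset Optional character vector of bin ids to restrict to.
#' @return Character vector of bin ids.
#' @export
environmental_overlap <- function(pm, meta, bin_subset = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  meta_f <- meta[match(colnames(pm$present), meta$sample_id), , drop = FALSE]
  soil <- which(meta_f$sample_type == "soil")
  if (length(soil) == 0L) {
    warning("no soil samples in metadata; environmental overlap is empty")
    return(character(0))
  }
  hits <- rownames(pm$present)[rowSums(pm$present[, soil, drop = FALSE]) > 0]
  if (!is.null(bin_subset)) hits <- intersect(bin_subset, hits)
  sort(hits)
}

#' Overlay chitinolytic status on a sharing report
#'
#' Splits every sharing category of \code{\link{summarize_sharing}} into the
#' chitinolytic subset (bins carrying at least one GH18 sequence with an
#' active chitinolytic site) and its complement, and counts detected
#' chitinolytic bins per host species.
#'
#' @param report A \code{sharing_report}.
#' @param chitinolytic Character vector of chitinolytic bin ids; must be a
#'   subset of the report's bins.
#' @return The report with an added \code{chitinolytic_overlay} element:
#'   \code{counts} (data.frame, category x chitinolytic/other),
#'   \code{per_species} (detected chitinolytic bins per host species) and
#'   \code{n_chitinolytic}.
#' @export
overlay_chitinolytic <- function(report, chitinolytic) {
  stopifnot(inherits(report, "sharing_report"))
  pb <- report$per_bin
  unknown <- setdiff(chitinolytic, pb$bin_id)
  if (length(unknown) > 0L) {
    stop("unknown bin id in chitinolytic set: '", unknown[1L], "'")
  }
  chi <- pb$bin_id %in% chitinolytic
  count_split <- function(flag) {
    c(chitinolytic = sum(flag & chi), other = sum(flag & !chi))
  }
  counts <- rbind(
    shared_beyond_source = count_split(pb$shared_beyond_source),
    single_sample = count_split(pb$single_sample),
    species_specific = count_split(pb$species_per_bin == 1),
    multi_species = count_split(pb$species_per_bin >= 2),
    single_order = count_split(pb$orders_per_bin == 1),
    multi_order = count_split(pb$orders_per_bin >= 2),
    undetected = count_split(pb$undetected)
  )
  counts <- as.data.frame(counts)
  per_species <- colSums(report$species_presence[chi, , drop = FALSE])
  report$chitinolytic_overlay <- list(counts = counts,
                                      per_species = per_species,
                                      n_chitinolytic = sum(chi))
  report
}
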