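#' Breadth and mean depth of coverage of one contig
#'
#' Breadth is the size of the union of depth >= 1 intervals (overlaps merged)
#' and mean depth is total covered bases divided by contig length.
#'
#' @param profile A \code{\link{depth_profile}}.
#' @param contig_id Contig identifier.
#' @param contig_length Contig length in bp.
#' @return List with \code{covered_bp} (integer) and \code{mean_depth}
#'   (numeric).
#' @export
contig_breadth <- function(profile, contig_id, contig_length) {
  stopifnot(inherits(profile, "depth_profile"), contig_length >= 1)
  iv <- profile$intervals
  iv <- iv[iv$contig == contig_id, , drop = FALSE]
  if (nrow(iv) == 0L) return(list(covered_bp = 0L, mean_depth = 0))
  if (any(iv$end > contig_length)) {
    stop("interval beyond contig '", contig_id, "' length ", contig_length)
  }
  pos <- iv[iv$depth >= 1L, , drop = FALSE]
  covered <- if (nrow(pos) == 0L) 0L else {
    # BED half-open [start, end) -> IRanges 1-based closed [start+1, end]
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = pos$start + 1L, end = pos$end))))
  }
  mean_depth <- sum(as.numeric(iv$depth) * (iv$end - iv$start)) / contig_length
  list(covered_bp = as.integer(covered), mean_depth = mean_depth)
}

#' Detection (breadth fraction) and mean coverage of a bin in one sample
#'
#' Detection is the fraction of bin positions covered by at least one read:
#' the sum of per-contig covered bases over the bin's total length. Mean
#' coverage is the length-weighted mean depth (total mapped bases on the bin
#' divided by bin length).
#'
#' @param profile A \code{\link{depth_profile}} for one sample.
#' @param contig_ids Member contig ids of the bin.
#' @param contig_lengths Named integer vector of contig lengths; every member
#'   contig must have a length.
#' @return List with \code{detection} in [0, 1] and \code{mean_coverage}.
#' @export
bin_detection <- function(profile, contig_ids, contig_lengths) {
  missing_len <- setdiff(contig_ids, names(contig_lengths))
  if (length(missing_len) > 0L) {
    stop("no length known for contig '", missing_len[1L], "'")
  }
  total <- sum(as.numeric(contig_lengths[contig_ids]))
  covered <- 0
  bases <- 0
  for (cid in contig_ids) {
    cb <- contig_breadth(profile, cid, contig_lengths[[cid]])
    covered <- covered + cb$covered_bp
    bases <- bases + cb$mean_depth * contig_lengths[[cid]]
  }
  list(detection = covered / total, mean_coverage = bases / total)
}

#' Detection matrix of bins across samples
#'
#' Computes per-bin, per-sample detection (breadth of coverage, in [0, 1])
#' and mean coverage from per-sample depth profiles.
#'
#' @param profiles Named list of \code{\link{depth_profile}} objects, one per
#'   sample (names are sample ids; unnamed lists use each profile's
#'   \code{sample_id}).
#' @param bins Bin data.frame with \code{bin_id} and list-column
#'   \code{contig_ids}.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return Object of class \code{detection_matrix}: list with
#'   \code{detection} and \code{mean_coverage} matrices (bins x samples),
#'   \code{bin_ids}, \code{sample_ids}.
#' @export
detection_matrix <- function(profiles, bins, contig_lengths) {
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) p$sample_id, character(1))
  }
  bin_ids <- bins$bin_id
  sample_ids <- names(profiles)
  det <- matrix(0, nrow = length(bin_ids), ncol = length(sample_ids),
                dimnames = list(bin_ids, sample_ids))
  cov <- det
  contigs_by_bin <- setNames(bins$contig_ids, bin_ids)
  for (sid in sample_ids) {
    prof <- profiles[[sid]]
    iv <- prof$intervals
    # per-contig covered bases and mapped bases, computed once per sample
    covered_by_contig <- numeric(0)
    if (nrow(iv) > 0L) {
      over <- iv$contig %in% names(contig_lengths) &
        iv$end > contig_lengths[iv$contig]
      if (any(over)) {
        bad <- which(over)[1L]
        stop("sample '", sid, "': interval beyond contig '", iv$contig[bad],
             "' length ", contig_lengths[[iv$contig[bad]]])
      }
      pos <- iv[iv$depth >= 1L, , drop = FALSE]
      if (nrow(pos) > 0L) {
        rl <- IRanges::IRangesList(split(
          IRanges::IRanges(start = pos$start + 1L, end = pos$end),
          pos$contig))
        covered_by_contig <- sum(IRanges::width(IRanges::reduce(rl)))
      }
    }
    bases_by_contig <- if (nrow(iv) > 0L) {
      tapply(as.numeric(iv$depth) * (iv$end - iv$start), iv$contig, sum)
    } else numeric(0)
    for (b in bin_ids) {
      cids <- contigs_by_bin[[b]]
      total <- sum(as.numeric(contig_lengths[cids]))
      cov_bp <- sum(covered_by_contig[intersect(cids, names(covered_by_contig))])
      bases <- sum(bases_by_contig[intersect(cids, names(bases_by_contig))])
      det[b, sid] <- cov_bp / total
      cov[b, sid] <- bases / total
    }
  }
  structure(list(detection = det, mean_coverage = cov,
                 bin_ids = bin_ids, sample_ids = sample_ids),
            class = "detection_matrix")
}

#' Call presence from a detection matrix
#'
#' A bin is present in a sample when its detection exceeds the threshold
#' (strictly by default, matching the ">0.25" convention used for detection
#' heatmaps; set \code{strict = FALSE} for >=). The default threshold 0.25
#' means a quarter of the genome's positions covered by at least one read.
#'
#' @param dm A \code{\link{detection_matrix}} or a numeric detection matrix.
#' @param threshold Detection threshold (default 0.25).
#' @param strict Use strict \code{>} (default TRUE); FALSE for \code{>=}.
#' @return Object of class \code{presence_matrix}: list with logical matrix
#'   \code{present}, \code{threshold}, \code{strict}, \code{bin_ids},
#'   \code{sample_ids}.
#' @export
call_presence <- function(dm, threshold = 0.25, strict = TRUE) {
  det <- if (inherits(dm, "detection_matrix")) dm$detection else as.matrix(dm)
  if (any(det < 0 | det > 1)) stop("detection values must lie in [0, 1]")
  present <- if (strict) det > threshold else det >= threshold
  structure(list(present = present, threshold = threshold, strict = strict,
                 bin_ids = rownames(det), sample_ids = colnames(det)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$present), "bins x", ncol(x$present),
      "samples;", sum(x$present), "presences at detection",
      if (x$strict) ">" else ">=", x$threshold, "\n")
  invisible(x)
}
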