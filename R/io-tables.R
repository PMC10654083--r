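#' Construct a per-sample depth profile
#'
#' A depth profile holds read-depth intervals for one sample in BED
#' convention: 0-based, half-open \code{[start, end)} coordinates.
#' Intervals on the same contig may overlap; union semantics apply when
#' breadth is computed.
#'
#' @param intervals A data.frame with columns \code{contig}, \code{start},
#'   \code{end}, \code{depth}.
#' @param sample_id Sample identifier.
#' @param contig_lengths Optional named integer vector of contig lengths used
#'   to validate interval bounds.
#' @return An object of class \code{depth_profile}.
#' @export
depth_profile <- function(intervals, sample_id = NA_character_,
                          contig_lengths = NULL) {
  req <- c("contig", "start", "end", "depth")
  if (!all(req %in% names(intervals))) {
    stop("depth intervals need columns: ", paste(req, collapse = ", "))
  }
  intervals <- intervals[, req, drop = FALSE]
  intervals$contig <- as.character(intervals$contig)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$depth <- as.integer(intervals$depth)
  bad <- which(is.na(intervals$start) | is.na(intervals$end) |
                 is.na(intervals$depth) | intervals$start < 0L |
                 intervals$start >= intervals$end | intervals$depth < 0L)
  if (length(bad) > 0L) {
    stop("invalid depth interval at row ", bad[1L],
         ": need 0 <= start < end and depth >= 0")
  }
  if (!is.null(contig_lengths)) {
    known <- intervals$contig %in% names(contig_lengths)
    over <- which(known & intervals$end > contig_lengths[intervals$contig])
    if (length(over) > 0L) {
      stop("depth interval at row ", over[1L], " extends beyond contig '",
           intervals$contig[over[1L]], "' length ",
           contig_lengths[[intervals$contig[over[1L]]]])
    }
  }
  structure(list(sample_id = sample_id, intervals = intervals),
            class = "depth_profile")
}

#' Read a BED-like per-sample depth file
#'
#' Expects a headerless 4+ column TSV: contig, start, end, depth with
#' 0-based half-open coordinates. An empty file yields a profile with zero
#' intervals (all depths implicitly 0).
#'
#' @param path Path to the TSV.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param contig_lengths Optional named integer vector for bounds validation.
#' @return A \code{\link{depth_profile}}.
#' @export
read_depth_bed <- function(path, sample_id = NULL, contig_lengths = NULL) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (file.size(path) == 0L) {
    iv <- data.frame(contig = character(), start = integer(),
                     end = integer(), depth = integer(),
                     stringsAsFactors = FALSE)
    return(depth_profile(iv, sample_id, contig_lengths))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("depth file ", path, " has fewer than 4 columns")
  names(tab)[1:4] <- c("contig", "start", "end", "depth")
  depth_profile(tab[, 1:4], sample_id, contig_lengths)
}

#' Read contig lengths
#'
#' @param path TSV with header columns \code{contig_id}, \code{length}.
#' @return Named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length") %in% names(tab)))
  setNames(as.integer(tab$length), tab$contig_id)
}

#' Read and cross-validate the bin map, QC table and sample metadata
#'
#' \code{bins.tsv} maps contigs to bins (columns \code{contig_id},
#' \code{bin_id}); \code{qc.tsv} carries per-bin quality metrics and
#' provenance (columns \code{bin_id}, \code{source_sample},
#' \code{assembly_origin}, \code{completeness}, \code{redundancy},
#' \code{n50}, \code{total_length}, \code{taxonomy}); \code{samples.tsv}
#' is the sample metadata (columns \code{sample_id}, \code{host_species},
#' \code{host_order}, \code{sample_type}).
#'
#' A contig assigned to two bins, or a bin whose \code{source_sample} is
#' absent from the metadata, is an error. A QC row for a bin absent from the
#' bin map produces a warning and the bin is skipped.
#'
#' @param bin_map,qc,metadata Paths to the three TSVs.
#' @param contig_lengths Optional named integer vector; when given,
#'   \code{total_length} is checked against the sum of member contig lengths.
#' @return A list with elements \code{bins} (data.frame, one row per bin,
#'   list-column \code{contig_ids}) and \code{samples} (data.frame).
#' @export
read_tables <- function(bin_map, qc, metadata, contig_lengths = NULL) {
  bm <- read.delim(bin_map, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "bin_id") %in% names(bm)))
  dup <- bm$contig_id[duplicated(bm$contig_id)]
  if (length(dup) > 0L) {
    stop("contig '", dup[1L], "' is assigned to more than one bin")
  }

  qt <- read.delim(qc, stringsAsFactors = FALSE)
  req <- c("bin_id", "source_sample", "assembly_origin", "completeness",
           "redundancy", "n50", "total_length", "taxonomy")
  missing_cols <- setdiff(req, names(qt))
  if (length(missing_cols) > 0L) {
    stop("qc table lacks columns: ", paste(missing_cols, collapse = ", "))
  }

  meta <- read_sample_metadata(metadata)

  orphan <- !(qt$bin_id %in% bm$bin_id)
  if (any(orphan)) {
    warning(sum(orphan), " QC row(s) for bins absent from the bin map were skipped: ",
            paste(utils::head(qt$bin_id[orphan], 5), collapse = ", "))
    qt <- qt[!orphan, , drop = FALSE]
  }
  unmapped <- setdiff(bm$bin_id, qt$bin_id)
  if (length(unmapped) > 0L) {
    stop("bin '", unmapped[1L], "' appears in the bin map but has no QC row")
  }
  unknown_sample <- setdiff(qt$source_sample, meta$sample_id)
  if (length(unknown_sample) > 0L) {
    stop("unknown source_sample '", unknown_sample[1L], "' in qc table")
  }

  contigs_by_bin <- split(bm$contig_id, bm$bin_id)[qt$bin_id]
  qt$contig_ids <- unname(contigs_by_bin)
  if (!is.null(contig_lengths)) {
    missing_len <- setdiff(bm$contig_id, names(contig_lengths))
    if (length(missing_len) > 0L) {
      stop("no length known for contig '", missing_len[1L], "'")
    }
    sums <- vapply(qt$contig_ids, function(ids) sum(contig_lengths[ids]),
                   numeric(1))
    off <- which(sums != qt$total_length)
    if (length(off) > 0L) {
      stop("bin '", qt$bin_id[off[1L]], "': total_length ",
           qt$total_length[off[1L]], " != sum of member contig lengths ",
           sums[off[1L]])
    }
  }
  rownames(qt) <- NULL
  list(bins = qt, samples = meta)
}

#' Read sample metadata
#'
#' @param path TSV with header columns \code{sample_id}, \code{host_species},
#'   \code{host_order}, \code{sample_type} (\code{fecal} or \code{soil}).
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "host_species", "host_order", "sample_type")
  stopifnot(all(req %in% names(meta)))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  bad_type <- setdiff(unique(meta$sample_type), c("fecal", "soil"))
  if (length(bad_type) > 0L) {
    stop("sample_type must be 'fecal' or 'soil', got '", bad_type[1L], "'")
  }
  fec <- meta$sample_type == "fecal"
  if (any(fec & (is.na(meta$host_species) | !nzchar(meta$host_species)))) {
    stop("fecal samples must declare a host_species")
  }
  meta
}

#' Write a bins-by-samples matrix as TSV
#'
#' First column \code{bin_id}, remaining columns one per sample.
#'
#' @param mat Numeric or logical matrix with bin row names and sample column
#'   names.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(bin_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bins-by-samples matrix written by \code{\link{write_matrix_tsv}}
#'
#' @param path TSV path (first column \code{bin_id}, header row of sample ids).
#' @return Matrix with bin row names and sample column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
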