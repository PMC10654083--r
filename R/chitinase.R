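#' Positional amino-acid motif
#'
#' The default pattern is the conserved GH18 chitinase active-site motif
#' DXXDXDXE: aspartate anchors at positions 1, 4 and 6 and the catalytic
#' glutamate at position 8, with \code{x} matching any residue. Anchor
#' positions match only their exact residue (ambiguity codes such as X, B or
#' Z never satisfy an anchor), while \code{x} positions match anything.
#'
#' @param pattern Pattern string; letters are anchors, \code{x}/\code{.}
#'   wildcards.
#' @return Object of class \code{aa_motif}.
#' @export
gh18_motif <- function(pattern = "DxxDxDxE") {
  chars <- strsplit(pattern, "")[[1]]
  if (length(chars) == 0L) stop("empty motif pattern")
  ok <- grepl("^[A-Zx.]$", chars)
  if (!all(ok)) stop("motif pattern may contain only A-Z anchors and x wildcards")
  regex <- paste(ifelse(chars %in% c("x", "."), ".", chars), collapse = "")
  structure(list(pattern = pattern, length = length(chars), regex = regex),
            class = "aa_motif")
}

#' Scan a protein for active-site motif matches
#'
#' Finds all (possibly overlapping) start positions of the motif in a
#' protein sequence. Matching is case-insensitive. Gap characters
#' (\code{-}) are removed before scanning by default, so aligned input can
#' be screened alignment-independently; with \code{degap = FALSE} the
#' aligned string is scanned as-is and a gap at any motif position is a
#' mismatch.
#'
#' @param protein Amino-acid string (may contain \code{-} gaps).
#' @param motif An \code{\link{gh18_motif}} object.
#' @param degap Remove gaps before scanning (default TRUE).
#' @return Integer vector of 1-based match start positions (empty when no
#'   match); positions index the scanned (ungapped, unless
#'   \code{degap = FALSE}) sequence.
#' @export
scan_active_site <- function(protein, motif = gh18_motif(), degap = TRUE) {
  stopifnot(inherits(motif, "aa_motif"), length(protein) == 1L)
  s <- toupper(protein)
  if (degap) s <- gsub("-", "", s, fixed = TRUE)
  if (!nzchar(s)) return(integer(0))
  # lookahead makes overlapping matches visible
  hits <- gregexpr(paste0("(?=", motif$regex, ")"), s, perl = TRUE)[[1]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits)
}

#' Screen a set of proteins for the active-site motif
#'
#' @param proteins data.frame with columns \code{id} and \code{sequence}
#'   (as from \code{\link{read_fasta}}).
#' @param seq2bin data.frame mapping \code{seq_id} to \code{bin_id}; every
#'   protein must be mapped.
#' @param motif An \code{\link{gh18_motif}}.
#' @param degap Remove gaps before scanning (default TRUE).
#' @return data.frame of GH18 records: \code{seq_id}, \code{bin_id},
#'   \code{n_motif_hits}, \code{active_site}, plus list-column
#'   \code{motif_hits} of 1-based start positions.
#' @export
screen_proteins <- function(proteins, seq2bin, motif = gh18_motif(),
                            degap = TRUE) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)),
            all(c("seq_id", "bin_id") %in% names(seq2bin)))
  idx <- match(proteins$id, seq2bin$seq_id)
  if (anyNA(idx)) {
    stop("protein '", proteins$id[which(is.na(idx))[1L]],
         "' has no bin mapping")
  }
  hits <- lapply(proteins$sequence, scan_active_site, motif = motif,
                 degap = degap)
  data.frame(
    seq_id = proteins$id,
    bin_id = seq2bin$bin_id[idx],
    n_motif_hits = lengths(hits),
    active_site = lengths(hits) > 0L,
    motif_hits = I(hits),
    stringsAsFactors = FALSE
  )
}

#' Mask low-occupancy alignment columns
#'
#' Keeps alignment columns whose non-gap fraction is at least
#' \code{min_occupancy} (inclusive, so "present in at least 50% of the
#' sequences" keeps a column at exactly 0.5). With \code{min_occupancy = 0}
#' this is the identity; with a value above 1 every column is removed.
#'
#' @param aln Named character vector (or data.frame from
#'   \code{\link{read_fasta}}) of equal-length aligned sequences with
#'   \code{-} gaps.
#' @param min_occupancy Minimum non-gap fraction per kept column (default
#'   0.5).
#' @return Object of class \code{masked_alignment}: list with
#'   \code{sequences} (named character), \code{kept_columns} (1-based
#'   original column indices) and \code{min_occupancy}.
#' @export
mask_alignment <- function(aln, min_occupancy = 0.5) {
  if (is.data.frame(aln)) aln <- setNames(aln$sequence, aln$id)
  widths <- nchar(aln)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(unname(aln), ""))
  occ <- colMeans(m != "-")
  keep <- which(occ >= min_occupancy)
  masked <- if (length(keep) == 0L) {
    setNames(rep("", length(aln)), names(aln))
  } else {
    setNames(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""),
             names(aln))
  }
  structure(list(sequences = masked, kept_columns = keep,
                 min_occupancy = min_occupancy),
            class = "masked_alignment")
}

#' Classify bins as chitinolytic
#'
#' A bin is chitinolytic when at least one of its GH18 records carries the
#' active-site motif. Bins with GH18 records but no active site are counted
#' but not classified as chitinolytic.
#'
#' @param records GH18 record data.frame from \code{\link{screen_proteins}}.
#' @param bin_ids Character vector of all bin ids (bins without records get
#'   zero counts).
#' @return List with \code{per_bin} (data.frame: bin_id, n_gh18,
#'   n_active, chitinolytic) and \code{chitinolytic_bins} (sorted character
#'   vector).
#' @export
classify_chitinolytic <- function(records, bin_ids) {
  unknown <- setdiff(records$bin_id, bin_ids)
  if (length(unknown) > 0L) {
    stop("GH18 record references unknown bin '", unknown[1L], "'")
  }
  n_gh18 <- table(factor(records$bin_id, levels = bin_ids))
  n_active <- table(factor(records$bin_id[records$active_site],
                           levels = bin_ids))
  per_bin <- data.frame(
    bin_id = bin_ids,
    n_gh18 = as.integer(n_gh18),
    n_active = as.integer(n_active),
    chitinolytic = as.integer(n_active) > 0L,
    stringsAsFactors = FALSE
  )
  list(per_bin = per_bin,
       chitinolytic_bins = sort(per_bin$bin_id[per_bin$chitinolytic]))
}
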