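#' MinHash sketch of a genome
#'
#' Computes a bottom-s MinHash sketch over the canonical k-mers of a set of
#' contig sequences (canonical k-mer = lexicographic minimum of a k-mer and
#' its reverse complement), as in the Mash genome-distance model. The sketch
#' is deterministic for a fixed sequence set, \code{k}, \code{s} and hash
#' seed, and identical for a genome and its reverse complement.
#'
#' k-mer windows containing non-ACGT characters are skipped; gap characters
#' (\code{-}) are removed before sketching.
#'
#' @param sequences Character vector of contig sequences (or a data.frame
#'   with a \code{sequence} column).
#' @param bin_id Optional genome/bin identifier stored in the sketch.
#' @param k K-mer size (1--32); default 21.
#' @param s Sketch size (number of retained minimum hash values); default
#'   1000.
#' @param seed Hash seed; default 42.
#' @return Object of class \code{mash_sketch} with fields \code{bin_id},
#'   \code{k}, \code{s}, \code{seed} and \code{hashes} (ascending, distinct).
#' @export
sketch_genome <- function(sequences, bin_id = NA_character_, k = 21,
                          s = 1000, seed = 42) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- gsub("-", "", as.character(sequences), fixed = TRUE)
  if (sum(nchar(sequences)) < k) {
    stop("genome", if (!is.na(bin_id)) paste0(" '", bin_id, "'"),
         " is shorter than k = ", k)
  }
  hashes <- .minhash_bottom_sketch(sequences, as.integer(k), as.integer(s),
                                   as.numeric(seed))
  structure(list(bin_id = bin_id, k = as.integer(k), s = as.integer(s),
                 seed = seed, hashes = hashes),
            class = "mash_sketch")
}

#' Mash-model ANI between two sketches
#'
#' The Jaccard index \eqn{j} is estimated on the merged bottom-s sketch of
#' the two hash sets; the Mash distance is
#' \eqn{d = -\log(2j / (1 + j)) / k} and ANI is reported as
#' \eqn{\max(0, 1 - d)} (0 when no hashes are shared). Containment,
#' \eqn{|A \cap B| / \min(|A|, |B|)}, is the sketch-level analogue of the
#' aligned genome fraction and is used to gate clustering decisions.
#'
#' @param a,b \code{mash_sketch} objects with equal \code{k}.
#' @return List with \code{ani}, \code{containment} and \code{jaccard}.
#' @export
mash_ani <- function(a, b) {
  stopifnot(inherits(a, "mash_sketch"), inherits(b, "mash_sketch"))
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  merged <- sort(unique(c(a$hashes, b$hashes)))
  su <- min(min(a$s, b$s), length(merged))
  merged <- merged[seq_len(su)]
  in_a <- merged %in% a$hashes
  in_b <- merged %in% b$hashes
  shared <- sum(in_a & in_b)
  j <- if (su > 0L) shared / su else 0
  if (j <= 0) {
    ani <- 0
  } else {
    d <- -log(2 * j / (1 + j)) / a$k
    ani <- max(0, 1 - d)
  }
  # containment estimated on the same merged bottom sketch (a uniform
  # sample of the k-mer union), so a short genome fully contained in a
  # longer one scores ~1 even though their Jaccard is small
  denom <- min(sum(in_a), sum(in_b))
  containment <- if (denom > 0L) shared / denom else 0
  list(ani = ani, containment = containment, jaccard = j)
}

#' Default dereplication genome score
#'
#' \code{completeness - 5 * redundancy + 0.5 * log10(n50)}; the
#' highest-scoring member of each secondary cluster is its representative.
#'
#' @param completeness,redundancy Percent values in [0, 100].
#' @param n50 Contig N50 in bp.
#' @return Numeric score.
#' @export
default_bin_score <- function(completeness, redundancy, n50) {
  completeness - 5 * redundancy + 0.5 * log10(n50)
}
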