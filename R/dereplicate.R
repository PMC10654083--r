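# union-find over 1..n with path compression; used for single-linkage
# components
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

.components <- function(n, edges) {
  parent <- seq_len(n)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      ri <- .uf_find(parent, edges[e, 1L])
      rj <- .uf_find(parent, edges[e, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
}

#' Two-stage ANI dereplication of genome bins
#'
#' Mirrors the common two-pass dereplication workflow: genomes are first
#' pre-filtered on length (> 50 kb) and quality (completeness > 75%,
#' redundancy < 25%), then clustered by single linkage at a primary ANI
#' threshold (default 90%), and each primary cluster is refined by single
#' linkage at a secondary ANI threshold (default 98%). Pairs whose sketch
#' containment falls below \code{min_containment} (the sketch-level analogue
#' of a 10% minimum aligned fraction) are treated as unrelated at both
#' stages. One representative per secondary cluster is chosen by
#' \code{scorer}, ties broken by lexicographically smaller \code{bin_id}.
#'
#' ANI here is the MinHash (Mash-model) estimate of
#' \code{\link{mash_ani}} — an approximation of alignment-based ANI that is
#' accurate in the 90--100% identity range where the thresholds operate.
#'
#' Clustering is deterministic and invariant to input order: bins are
#' canonically sorted by id and clusters are labelled by their
#' lexicographically smallest member.
#'
#' @param bins Bin QC data.frame (columns \code{bin_id}, \code{completeness},
#'   \code{redundancy}, \code{n50}, \code{total_length}).
#' @param genomes Named list mapping \code{bin_id} to a character vector of
#'   contig sequences.
#' @param ani_primary Primary clustering ANI threshold (default 0.90).
#' @param ani_secondary Secondary threshold (default 0.98).
#' @param min_containment Minimum sketch containment for a pair to be
#'   linkable (default 0.10).
#' @param k,s,seed Sketch parameters passed to \code{\link{sketch_genome}}.
#' @param prefilter Apply the length/quality pre-filters (default TRUE).
#' @param scorer Function(completeness, redundancy, n50) -> score; default
#'   \code{\link{default_bin_score}}.
#' @return Object of class \code{cluster_set}: a list with \code{clusters}
#'   (data.frame: bin_id, primary_cluster, secondary_cluster, score,
#'   is_representative), \code{representatives} (character vector),
#'   \code{excluded} (data.frame of pre-filtered bins and reasons) and
#'   \code{params}.
#' @export
dereplicate <- function(bins, genomes, ani_primary = 0.90,
                        ani_secondary = 0.98, min_containment = 0.10,
                        k = 21, s = 1000, seed = 42, prefilter = TRUE,
                        scorer = default_bin_score) {
  stopifnot(nrow(bins) >= 1L)
  req <- c("bin_id", "completeness", "redundancy", "n50", "total_length")
  stopifnot(all(req %in% names(bins)))
  missing_seq <- setdiff(bins$bin_id, names(genomes))
  if (length(missing_seq) > 0L) {
    stop("no sequences provided for bin '", missing_seq[1L], "'")
  }

  excluded <- data.frame(bin_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (prefilter) {
    fail_len <- bins$total_length <= 50000
    fail_comp <- bins$completeness <= 75
    fail_red <- bins$redundancy >= 25
    drop <- fail_len | fail_comp | fail_red
    if (any(drop)) {
      reason <- ifelse(fail_len, "length <= 50 kb",
                       ifelse(fail_comp, "completeness <= 75%",
                              "redundancy >= 25%"))
      excluded <- data.frame(bin_id = bins$bin_id[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE)
      bins <- bins[!drop, , drop = FALSE]
    }
    if (nrow(bins) == 0L) {
      stop("no bins passed the dereplication pre-filters")
    }
  }

  # canonical order makes clustering independent of input permutation
  bins <- bins[order(bins$bin_id), , drop = FALSE]
  ids <- bins$bin_id
  n <- length(ids)

  sketches <- lapply(seq_len(n), function(i) {
    sketch_genome(genomes[[ids[i]]], bin_id = ids[i], k = k, s = s,
                  seed = seed)
  })

  ani <- matrix(1, n, n)
  cont <- matrix(1, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m <- mash_ani(sketches[[i]], sketches[[j]])
        ani[i, j] <- ani[j, i] <- m$ani
        cont[i, j] <- cont[j, i] <- m$containment
      }
    }
  }

  linkable <- function(threshold) {
    which(upper.tri(ani) & ani >= threshold & cont >= min_containment,
          arr.ind = TRUE)
  }

  prim_comp <- .components(n, linkable(ani_primary))
  sec_comp_raw <- .components(n, linkable(ani_secondary))
  # secondary refines primary by construction (ani_secondary >= ani_primary
  # links are a subset of primary links when thresholds are ordered); combine
  # defensively so the invariant holds for any threshold pair
  sec_comp <- as.integer(factor(paste(prim_comp, sec_comp_raw)))

  label_of <- function(comp, prefix) {
    first_member <- tapply(ids, comp, min)
    lab <- setNames(sprintf("%s%03d", prefix,
                            seq_along(sort(unname(first_member)))),
                    sort(unname(first_member)))
    lab[unname(first_member[as.character(comp)])]
  }
  primary_lab <- label_of(prim_comp, "P")
  secondary_lab <- label_of(sec_comp, "S")

  score <- scorer(bins$completeness, bins$redundancy, bins$n50)
  clusters <- data.frame(bin_id = ids,
                         primary_cluster = unname(primary_lab),
                         secondary_cluster = unname(secondary_lab),
                         score = score,
                         stringsAsFactors = FALSE)
  reps <- vapply(split(clusters, clusters$secondary_cluster), function(cl) {
    best <- cl[cl$score == max(cl$score), , drop = FALSE]
    min(best$bin_id)
  }, character(1))
  clusters$is_representative <- clusters$bin_id %in% reps
  rownames(clusters) <- NULL

  structure(list(clusters = clusters,
                 representatives = sort(unname(reps)),
                 excluded = excluded,
                 params = list(ani_primary = ani_primary,
                               ani_secondary = ani_secondary,
                               min_containment = min_containment,
                               k = k, s = s, seed = seed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$clusters), "bins,",
      length(unique(x$clusters$primary_cluster)), "primary clusters,",
      length(unique(x$clusters$secondary_cluster)), "secondary clusters,",
      length(x$representatives), "representatives;",
      nrow(x$excluded), "excluded by pre-filters\n")
  invisible(x)
}
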