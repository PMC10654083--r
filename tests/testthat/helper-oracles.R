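# Independent brute-force oracles used across tests. These deliberately use
# the most naive correct computation (per-position counting, exhaustive
# window scans, set enumeration) so they share no code with the package
# paths they check.

# per-position breadth/depth of one contig
oracle_contig_breadth <- function(intervals, contig_len) {
  depth <- integer(contig_len)
  for (r in seq_len(nrow(intervals))) {
    idx <- seq(intervals$start[r] + 1L, intervals$end[r])
    depth[idx] <- depth[idx] + intervals$depth[r]
  }
  list(covered_bp = sum(depth >= 1L), mean_depth = sum(depth) / contig_len)
}

# per-position detection and mean coverage of a bin across its contigs
oracle_bin_detection <- function(intervals, contig_lengths, contig_ids) {
  covered <- 0L
  bases <- 0
  for (cid in contig_ids) {
    iv <- intervals[intervals$contig == cid, , drop = FALSE]
    cb <- oracle_contig_breadth(iv, contig_lengths[[cid]])
    covered <- covered + cb$covered_bp
    bases <- bases + cb$mean_depth * contig_lengths[[cid]]
  }
  total <- sum(contig_lengths[contig_ids])
  list(detection = covered / total, mean_coverage = bases / total)
}

# exhaustive sliding-window motif scan; pattern chars, "x" = wildcard
oracle_motif_scan <- function(protein, pattern = "DxxDxDxE") {
  s <- strsplit(toupper(gsub("-", "", protein)), "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(s) >= length(p)) {
    for (i in seq_len(length(s) - length(p) + 1L)) {
      ok <- TRUE
      for (j in seq_along(p)) {
        if (p[j] != "x" && s[i + j - 1L] != p[j]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# set-arithmetic enumeration of all sharing categories
oracle_sharing <- function(present, src, species, orders) {
  bins <- rownames(present)
  stats <- lapply(bins, function(b) {
    det <- colnames(present)[present[b, ]]
    list(n_samples = length(det),
         n_species = length(unique(species[det])),
         n_orders = length(unique(orders[det])),
         shared = length(setdiff(det, src[[b]])) > 0)
  })
  n_samples <- vapply(stats, `[[`, numeric(1), "n_samples")
  n_species <- vapply(stats, `[[`, numeric(1), "n_species")
  n_orders <- vapply(stats, `[[`, numeric(1), "n_orders")
  list(
    n_undetected = sum(n_samples == 0),
    n_single_sample = sum(n_samples == 1),
    n_shared_beyond_source = sum(vapply(stats, `[[`, logical(1), "shared")),
    n_species_specific = sum(n_species == 1),
    n_multi_species = sum(n_species >= 2),
    n_single_order = sum(n_orders == 1),
    n_multi_order = sum(n_orders >= 2),
    mean_samples_per_bin = mean(n_samples),
    mean_species_per_bin = mean(n_species),
    mean_orders_per_bin = mean(n_orders),
    samples_per_bin = setNames(n_samples, bins)
  )
}

# random depth fixture: one contig set, random (possibly overlapping,
# possibly zero-depth) intervals
random_depth_fixture <- function(n_contigs = 3, len_range = c(80, 300),
                                 max_intervals = 6) {
  lens <- sample(seq(len_range[1], len_range[2]), n_contigs, replace = TRUE)
  contig_lengths <- setNames(lens, sprintf("c%d", seq_len(n_contigs)))
  rows <- list()
  for (cid in names(contig_lengths)) {
    for (k in seq_len(sample.int(max_intervals, 1))) {
      len <- contig_lengths[[cid]]
      a <- sample.int(len, 1L) - 1L
      b <- min(len, a + sample.int(60, 1L))
      if (a < b) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cid, start = a, end = b,
          depth = sample(0:3, 1), stringsAsFactors = FALSE)
      }
    }
  }
  list(contig_lengths = contig_lengths,
       intervals = do.call(rbind, rows))
}

# random presence fixture with sample metadata
random_presence_fixture <- function(n_bins = 12, n_species = 3,
                                    samples_per_species = 2, n_soil = 2) {
  species <- sprintf("sp%d", seq_len(n_species))
  ord <- setNames(sprintf("ord%d", (seq_len(n_species) - 1) %% 2 + 1), species)
  fecal <- do.call(rbind, lapply(species, function(s) {
    data.frame(sample_id = sprintf("%s_s%d", s, seq_len(samples_per_species)),
               host_species = s, host_order = ord[[s]],
               sample_type = "fecal", stringsAsFactors = FALSE)
  }))
  soil <- if (n_soil > 0) data.frame(
    sample_id = sprintf("soil%d", seq_len(n_soil)), host_species = "",
    host_order = "", sample_type = "soil", stringsAsFactors = FALSE) else NULL
  meta <- rbind(fecal, soil)
  bins <- data.frame(bin_id = sprintf("b%02d", seq_len(n_bins)),
                     source_sample = sample(fecal$sample_id, n_bins,
                                            replace = TRUE),
                     stringsAsFactors = FALSE)
  det <- matrix(runif(n_bins * nrow(meta)), n_bins, nrow(meta),
                dimnames = list(bins$bin_id, meta$sample_id))
  list(meta = meta, bins = bins, detection = det)
}

random_protein <- function(len = 200) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}
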