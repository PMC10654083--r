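# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.BASES <- c("A", "C", "G", "T")

#' Random nucleotide sequence
#'
#' @param len Length in bp.
#' @return Character scalar of uniform random ACGT.
#' @export
random_genome <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

#' Mutate a genome by independent per-site substitution
#'
#' Each site is substituted independently with probability \code{p_sub} to a
#' uniformly chosen different base, so expected identity to the input is
#' \code{1 - p_sub}.
#'
#' @param sequence Nucleotide string.
#' @param p_sub Per-site substitution probability in [0, 0.75).
#' @param seed Optional seed for a reproducible mutation pattern (the
#'   caller's RNG state is preserved).
#' @return Mutated sequence string.
#' @export
mutate_genome <- function(sequence, p_sub, seed = NULL) {
  stopifnot(p_sub >= 0, p_sub < 0.75)
  run <- function() {
    chars <- strsplit(sequence, "")[[1]]
    hit <- which(runif(length(chars)) < p_sub)
    if (length(hit) > 0L) {
      cur <- match(chars[hit], .BASES)
      step <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- .BASES[((cur - 1L + step) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Specification of a synthetic gut-metagenome community
#'
#' Defaults emulate the shape of a field study of myrmecophagous mammal gut
#' microbiomes: 29 fecal samples from 9 host species in 5 placental orders
#' plus 8 soil control samples; a mixture of generalist bins (shared across
#' host species) and specialist bins (confined to their source species);
#' roughly 42% of bins carrying 1--17 GH18 sequences of which about 62%
#' carry at least one active-site motif; present bins drawing detection
#' from Beta(50, 5) (mean ~0.91) and absent bins from Beta(1, 99)
#' (mean ~0.01), far on either side of the 0.25 presence threshold.
#'
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   seed.
#' @param species Named character vector mapping host species to host order.
#' @param samples_per_species Named integer vector of fecal sample counts
#'   per species (names must match \code{species}).
#' @param n_soil Number of soil control samples.
#' @param n_bins Number of high-quality bins to plant.
#' @param n_lowq Number of low-quality decoy bins (fail the completeness or
#'   redundancy filter).
#' @param contigs_per_bin Contigs per genome bin.
#' @param genome_len Genome length in bp.
#' @param frac_generalist Fraction of bins planted as generalists.
#' @param p_shared_other Per-sample presence probability of a generalist in
#'   non-source fecal samples.
#' @param p_conspecific Per-sample presence probability of a specialist in
#'   other samples of its source species.
#' @param frac_undetected Fraction of bins planted as never detected.
#' @param frac_soil Fraction of bins also planted in soil samples.
#' @param frac_gh18 Fraction of bins carrying GH18 sequences.
#' @param frac_active_given_gh18 Fraction of GH18-carrying bins given at
#'   least one active-site sequence.
#' @param gh18_per_bin_max Maximum GH18 sequences per bin.
#' @param detection_present,detection_absent Beta(a, b) parameters for the
#'   planted detection of present / absent bins.
#' @param divergence_groups Optional data.frame with columns \code{size} and
#'   \code{p_sub}: the first \code{sum(size)} bins are built as groups of
#'   mutated copies of a shared base genome (ground truth for
#'   dereplication); remaining bins are independent random genomes.
#' @return Object of class \code{community_spec}.
#' @export
community_spec <- function(
    seed = 1,
    species = c(T_tetradactyla = "Pilosa", M_tridactyla = "Pilosa",
                D_novemcinctus = "Cingulata", D_kappleri = "Cingulata",
                D_sp_nov = "Cingulata", C_unicinctus = "Cingulata",
                S_temminckii = "Pholidota", O_afer = "Tubulidentata",
                P_cristata = "Carnivora"),
    samples_per_species = c(T_tetradactyla = 3, M_tridactyla = 2,
                            D_novemcinctus = 2, D_kappleri = 1,
                            D_sp_nov = 4, C_unicinctus = 2,
                            S_temminckii = 6, O_afer = 3, P_cristata = 6),
    n_soil = 8, n_bins = 60, n_lowq = 6, contigs_per_bin = 2,
    genome_len = 250000, frac_generalist = 0.6, p_shared_other = 0.2,
    p_conspecific = 0.5, frac_undetected = 0.015, frac_soil = 0.29,
    frac_gh18 = 0.42, frac_active_given_gh18 = 0.62, gh18_per_bin_max = 17,
    detection_present = c(50, 5), detection_absent = c(1, 99),
    divergence_groups = NULL) {
  fracs <- c(frac_generalist, frac_undetected, frac_soil, frac_gh18,
             frac_active_given_gh18, p_shared_other, p_conspecific)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            all(names(samples_per_species) %in% names(species)),
            n_bins >= 1, genome_len >= 100, contigs_per_bin >= 1,
            length(detection_present) == 2, length(detection_absent) == 2)
  if (!is.null(divergence_groups)) {
    stopifnot(all(c("size", "p_sub") %in% names(divergence_groups)),
              sum(divergence_groups$size) <= n_bins)
  }
  spec <- as.list(environment())
  structure(spec, class = "community_spec")
}

# sample ids: Ttet_S1 ... ; soil SOIL_1 ...
.make_samples <- function(spec) {
  sp <- names(spec$samples_per_species)
  fecal <- do.call(rbind, lapply(sp, function(s) {
    n <- spec$samples_per_species[[s]]
    data.frame(sample_id = sprintf("%s_S%d", gsub("_", "", s), seq_len(n)),
               host_species = s, host_order = spec$species[[s]],
               sample_type = "fecal", stringsAsFactors = FALSE)
  }))
  soil <- if (spec$n_soil > 0) {
    data.frame(sample_id = sprintf("SOIL_%d", seq_len(spec$n_soil)),
               host_species = "", host_order = "", sample_type = "soil",
               stringsAsFactors = FALSE)
  } else NULL
  rbind(fecal, soil)
}

# depth rows realising one planted detection value on one contig: a single
# covered window of round(d * len) positions, split into 1-3 sub-intervals
# of Poisson(4)+1 depth
.plant_coverage <- function(contig, len, d) {
  w <- round(d * len)
  if (w < 1L) return(NULL)
  start <- if (w >= len) 0L else sample.int(len - w, 1L) - 1L
  n_parts <- sample.int(min(3L, w), 1L)
  cuts <- sort(unique(c(0L, w, if (n_parts > 1L)
    sample.int(w - 1L, n_parts - 1L))))
  data.frame(contig = contig,
             start = start + cuts[-length(cuts)],
             end = start + cuts[-1L],
             depth = rpois(length(cuts) - 1L, 4) + 1L,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic community bundle with ground truth
#'
#' Builds genomes, bin/QC/sample tables, per-sample depth profiles realising
#' a planted presence structure, GH18 protein sequences with planted
#' active-site motifs, and a \code{truth} record of every planted quantity
#' (presence matrix, sharing categories, ANI groups, chitinolytic set, soil
#' overlap). Deterministic for a fixed \code{spec$seed}: two runs produce
#' identical bundles (and identical files when \code{out_dir} is given).
#'
#' @param spec A \code{\link{community_spec}}.
#' @param out_dir Optional directory; when given, the bundle is written as
#'   plain-text files (genomes.fasta, bins.tsv, qc.tsv, samples.tsv,
#'   contigs.tsv, depth/<sample>.tsv, gh18.faa, seq2bin.tsv, truth.json).
#' @return The bundle, invisibly when written: a list with \code{spec},
#'   \code{samples}, \code{bins}, \code{contig_lengths}, \code{genomes},
#'   \code{profiles}, \code{proteins}, \code{seq2bin}, \code{truth}.
#' @export
generate_community <- function(spec = community_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  bundle <- .with_seed(spec$seed, .generate_community_impl(spec))
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

.generate_community_impl <- function(spec) {
  samples <- .make_samples(spec)
  fecal_ids <- samples$sample_id[samples$sample_type == "fecal"]
  soil_ids <- samples$sample_id[samples$sample_type == "soil"]
  n_total <- spec$n_bins + spec$n_lowq
  bin_ids <- sprintf("bin_%03d", seq_len(n_total))
  hq <- seq_len(spec$n_bins)

  # genomes: divergence groups first (shared base genome, mutated copies),
  # then independent random genomes
  ani_group <- integer(n_total)
  genome_seq <- character(n_total)
  next_bin <- 1L
  group_id <- 0L
  if (!is.null(spec$divergence_groups)) {
    for (g in seq_len(nrow(spec$divergence_groups))) {
      group_id <- group_id + 1L
      base <- random_genome(spec$genome_len)
      for (m in seq_len(spec$divergence_groups$size[g])) {
        genome_seq[next_bin] <- if (m == 1L) base else
          mutate_genome(base, spec$divergence_groups$p_sub[g])
        ani_group[next_bin] <- group_id
        next_bin <- next_bin + 1L
      }
    }
  }
  while (next_bin <= n_total) {
    group_id <- group_id + 1L
    genome_seq[next_bin] <- random_genome(spec$genome_len)
    ani_group[next_bin] <- group_id
    next_bin <- next_bin + 1L
  }

  # split each genome into contigs (fixed 60/40-style uneven split pattern)
  contig_ids <- list()
  contig_lengths <- integer(0)
  contig_seqs <- character(0)
  genomes <- list()
  for (i in seq_len(n_total)) {
    len <- spec$genome_len
    ncon <- spec$contigs_per_bin
    bounds <- unique(round(seq(0, len, length.out = ncon + 1L) +
                             c(0, runif(max(ncon - 1L, 0), -0.1, 0.1) * len / ncon, 0)))
    bounds <- sort(pmin(pmax(bounds, 0), len))
    if (length(bounds) < 2L) bounds <- c(0L, len)
    ids <- sprintf("%s_c%d", bin_ids[i], seq_len(length(bounds) - 1L))
    seqs <- substring(genome_seq[i], bounds[-length(bounds)] + 1L, bounds[-1L])
    contig_ids[[i]] <- ids
    contig_lengths <- c(contig_lengths, setNames(nchar(seqs), ids))
    contig_seqs <- c(contig_seqs, setNames(seqs, ids))
    genomes[[bin_ids[i]]] <- unname(seqs)
  }

  # QC table: high-quality bins pass >90 / <5; decoys fail one criterion
  completeness <- round(runif(n_total, 91, 99.9), 1)
  redundancy <- round(runif(n_total, 0, 4.5), 1)
  if (spec$n_lowq > 0) {
    lowq <- seq(spec$n_bins + 1L, n_total)
    fail_comp <- lowq[seq_along(lowq) %% 2L == 1L]
    fail_red <- setdiff(lowq, fail_comp)
    completeness[fail_comp] <- round(runif(length(fail_comp), 60, 89.5), 1)
    redundancy[fail_red] <- round(runif(length(fail_red), 5.5, 15), 1)
  }
  source_sample <- sample(fecal_ids, n_total, replace = TRUE)
  bins <- data.frame(
    bin_id = bin_ids,
    source_sample = source_sample,
    assembly_origin = sample(c("long_read", "short_read"), n_total,
                             replace = TRUE),
    completeness = completeness,
    redundancy = redundancy,
    n50 = vapply(contig_ids, function(ids) max(contig_lengths[ids]),
                 numeric(1)),
    total_length = vapply(contig_ids, function(ids)
      sum(contig_lengths[ids]), numeric(1)),
    taxonomy = sprintf(
      "d__Bacteria;p__P%02d;c__;o__;f__F%02d;g__;s__",
      ani_group %% 7L + 1L, ani_group %% 15L + 1L),
    stringsAsFactors = FALSE
  )
  bins$contig_ids <- contig_ids

  # planted presence over fecal samples (generalist / specialist /
  # undetected) and soil
  sample_species <- setNames(samples$host_species, samples$sample_id)
  role <- ifelse(runif(n_total) < spec$frac_undetected, "undetected",
                 ifelse(runif(n_total) < spec$frac_generalist,
                        "generalist", "specialist"))
  presence <- matrix(FALSE, n_total, length(fecal_ids),
                     dimnames = list(bin_ids, fecal_ids))
  for (i in seq_len(n_total)) {
    if (role[i] == "undetected") next
    src <- source_sample[i]
    presence[i, src] <- TRUE
    others <- setdiff(fecal_ids, src)
    if (role[i] == "generalist") {
      presence[i, others] <- runif(length(others)) < spec$p_shared_other
    } else {
      consp <- others[sample_species[others] == sample_species[[src]]]
      if (length(consp) > 0) {
        presence[i, consp] <- runif(length(consp)) < spec$p_conspecific
      }
    }
  }
  soil_presence <- matrix(FALSE, n_total, length(soil_ids),
                          dimnames = list(bin_ids, soil_ids))
  if (length(soil_ids) > 0) {
    in_soil <- runif(n_total) < spec$frac_soil & role != "undetected"
    for (i in which(in_soil)) {
      hits <- runif(length(soil_ids)) < 0.3
      if (!any(hits)) hits[sample.int(length(soil_ids), 1L)] <- TRUE
      soil_presence[i, ] <- hits
    }
  }

  # depth profiles realising the planted presence with Beta-distributed
  # detection
  planted_detection <- matrix(0, n_total, nrow(samples),
                              dimnames = list(bin_ids, samples$sample_id))
  profiles <- list()
  for (sid in samples$sample_id) {
    rows <- list()
    is_soil <- sid %in% soil_ids
    for (i in seq_len(n_total)) {
      pres <- if (is_soil) soil_presence[i, sid] else presence[i, sid]
      pars <- if (pres) spec$detection_present else spec$detection_absent
      d <- rbeta(1, pars[1], pars[2])
      realized <- 0
      for (cid in contig_ids[[i]]) {
        iv <- .plant_coverage(cid, contig_lengths[[cid]], d)
        if (!is.null(iv)) {
          rows[[length(rows) + 1L]] <- iv
          realized <- realized + (iv$end[nrow(iv)] - iv$start[1L])
        }
      }
      planted_detection[i, sid] <- realized / sum(contig_lengths[contig_ids[[i]]])
    }
    iv <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 depth = integer(), stringsAsFactors = FALSE)
    profiles[[sid]] <- depth_profile(iv, sid, contig_lengths)
  }

  # GH18 proteins with planted active-site motifs (high-quality bins only)
  has_gh18 <- runif(n_total) < spec$frac_gh18 & seq_len(n_total) %in% hq
  active_bin <- has_gh18 & runif(n_total) < spec$frac_active_given_gh18
  prot_rows <- list()
  motif <- gh18_motif()
  for (i in which(has_gh18)) {
    n_seq <- min(1L + rpois(1, 1.5), spec$gh18_per_bin_max)
    n_act <- if (active_bin[i]) 1L + rbinom(1, n_seq - 1L, 0.4) else 0L
    for (j in seq_len(n_seq)) {
      id <- sprintf("%s_gh18_%d", bin_ids[i], j)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        seq_id = id, bin_id = bin_ids[i],
        sequence = .make_protein(active = j <= n_act, motif = motif),
        stringsAsFactors = FALSE)
    }
  }
  proteins <- if (length(prot_rows) > 0) do.call(rbind, prot_rows) else
    data.frame(seq_id = character(), bin_id = character(),
               sequence = character(), stringsAsFactors = FALSE)

  truth <- .compute_truth(spec, bin_ids[hq], bins, samples, presence[hq, ,
                          drop = FALSE], soil_presence[hq, , drop = FALSE],
                          ani_group[hq], proteins, active_bin, role)
  bundle <- list(
    spec = spec, samples = samples, bins = bins,
    contig_lengths = contig_lengths, contig_seqs = contig_seqs,
    genomes = genomes, profiles = profiles,
    proteins = data.frame(id = proteins$seq_id,
                          sequence = proteins$sequence,
                          stringsAsFactors = FALSE),
    seq2bin = proteins[, c("seq_id", "bin_id")],
    planted_detection = planted_detection,
    truth = truth
  )
  class(bundle) <- "community_bundle"
  bundle
}

# random protein of length 300; active ones get the 8-residue motif planted
# at a random offset, inactive ones are rejection-sampled to be motif-free
.make_protein <- function(active, motif, len = 300L) {
  repeat {
    aa <- sample(.AA20, len, replace = TRUE)
    s <- paste(aa, collapse = "")
    if (!active) {
      if (length(scan_active_site(s, motif)) == 0L) return(s)
      next
    }
    off <- sample.int(len - motif$length + 1L, 1L)
    chars <- strsplit(motif$pattern, "")[[1]]
    planted <- ifelse(chars == "x", sample(.AA20, motif$length, replace = TRUE),
                      chars)
    aa[off:(off + motif$length - 1L)] <- planted
    return(paste(aa, collapse = ""))
  }
}

# independent enumeration of every planted category (ground truth record)
.compute_truth <- function(spec, hq_ids, bins, samples, presence,
                           soil_presence, ani_group, proteins, active_bin,
                           role) {
  fecal <- samples[samples$sample_type == "fecal", , drop = FALSE]
  sp_of <- setNames(fecal$host_species, fecal$sample_id)
  or_of <- setNames(fecal$host_order, fecal$sample_id)
  src <- setNames(bins$source_sample, bins$bin_id)[hq_ids]

  n_samples <- apply(presence, 1L, sum)
  n_species <- apply(presence, 1L, function(p)
    length(unique(sp_of[colnames(presence)[p]])))
  n_orders <- apply(presence, 1L, function(p)
    length(unique(or_of[colnames(presence)[p]])))
  shared <- vapply(hq_ids, function(b)
    any(presence[b, setdiff(colnames(presence), src[[b]])]), logical(1))

  gh18_by_bin <- table(factor(proteins$bin_id, levels = hq_ids))
  chitinolytic <- hq_ids[active_bin[match(hq_ids, bins$bin_id)]]

  list(
    seed = spec$seed,
    selected_bins = hq_ids,
    lowq_bins = setdiff(bins$bin_id, hq_ids),
    role = setNames(role[match(hq_ids, bins$bin_id)], hq_ids),
    presence = presence,
    soil_presence = soil_presence,
    n_bins = length(hq_ids),
    n_undetected = sum(n_samples == 0),
    n_single_sample = sum(n_samples == 1),
    n_shared_beyond_source = sum(shared),
    n_species_specific = sum(n_species == 1),
    n_multi_species = sum(n_species >= 2),
    n_single_order = sum(n_orders == 1),
    n_multi_order = sum(n_orders >= 2),
    mean_samples_per_bin = mean(n_samples),
    mean_species_per_bin = mean(n_species),
    mean_orders_per_bin = mean(n_orders),
    soil_overlap_bins = sort(hq_ids[apply(soil_presence, 1L, any)]),
    ani_group = setNames(ani_group, hq_ids),
    gh18_per_bin = setNames(as.integer(gh18_by_bin), hq_ids),
    n_gh18_bins = sum(gh18_by_bin > 0),
    chitinolytic_bins = sort(chitinolytic)
  )
}

#' Write a community bundle to plain-text files
#'
#' @param bundle A bundle from \code{\link{generate_community}}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_fasta(data.frame(id = names(bundle$contig_seqs),
                         sequence = unname(bundle$contig_seqs),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "genomes.fasta"))
  bin_map <- do.call(rbind, lapply(seq_len(nrow(bundle$bins)), function(i) {
    data.frame(contig_id = bundle$bins$contig_ids[[i]],
               bin_id = bundle$bins$bin_id[i], stringsAsFactors = FALSE)
  }))
  tsv(bin_map, "bins.tsv")
  qc <- bundle$bins[, c("bin_id", "source_sample", "assembly_origin",
                        "completeness", "redundancy", "n50", "total_length",
                        "taxonomy")]
  qc$completeness <- sprintf("%.1f", qc$completeness)
  qc$redundancy <- sprintf("%.1f", qc$redundancy)
  tsv(qc, "qc.tsv")
  tsv(bundle$samples, "samples.tsv")
  tsv(data.frame(contig_id = names(bundle$contig_lengths),
                 length = unname(bundle$contig_lengths),
                 stringsAsFactors = FALSE), "contigs.tsv")
  for (sid in names(bundle$profiles)) {
    write.table(bundle$profiles[[sid]]$intervals,
                file.path(out_dir, "depth", paste0(sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (nrow(bundle$proteins) > 0) {
    write_fasta(bundle$proteins, file.path(out_dir, "gh18.faa"))
  } else {
    file.create(file.path(out_dir, "gh18.faa"))
  }
  tsv(bundle$seq2bin, "seq2bin.tsv")
  truth <- bundle$truth
  truth$presence <- list(bin_ids = rownames(truth$presence),
                         sample_ids = colnames(truth$presence),
                         values = unname(apply(truth$presence, 1L, as.integer,
                                               simplify = FALSE)))
  truth$soil_presence <- list(
    bin_ids = rownames(bundle$truth$soil_presence),
    sample_ids = colnames(bundle$truth$soil_presence),
    values = unname(apply(bundle$truth$soil_presence, 1L, as.integer,
                          simplify = FALSE)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
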