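# run a stage with its name prefixed onto any error
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full comparative MAG pipeline on a bundle directory
#'
#' Reads a bundle as written by \code{\link{generate_community}} (or
#' assembled from real data in the same layout: \code{bins.tsv},
#' \code{qc.tsv}, \code{samples.tsv}, \code{contigs.tsv},
#' \code{genomes.fasta}, \code{depth/<sample>.tsv}, \code{gh18.faa},
#' \code{seq2bin.tsv}) and runs, in order: high-quality bin selection,
#' two-stage ANI dereplication, breadth-of-coverage detection across all
#' samples, presence calling, sharing/host-specificity statistics with the
#' chitinolytic overlay, environmental (soil) overlap, and GH18 active-site
#' screening.
#'
#' @param input_dir Bundle directory.
#' @param out_dir Optional output directory; stage outputs and a manifest
#'   are written there.
#' @param threshold Detection threshold for presence calls (default 0.25).
#' @param strict Strict \code{>} presence rule (default TRUE).
#' @param qc A \code{\link{quality_thresholds}} object.
#' @param ani_primary,ani_secondary,min_containment,k,s,sketch_seed
#'   Dereplication parameters (see \code{\link{dereplicate}}).
#' @param run_derep Run the dereplication stage (default TRUE); when FALSE
#'   all selected bins are carried forward.
#' @param include_undetected Include never-detected bins in report means.
#' @return Invisibly, a list with elements \code{selected}, \code{clusters},
#'   \code{bins_final}, \code{dm} (detection matrix), \code{pm} (presence),
#'   \code{report} (sharing report with chitinolytic overlay),
#'   \code{gh18} (records), \code{chitinolytic} (classification),
#'   \code{soil_overlap} and \code{manifest}.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, threshold = 0.25,
                         strict = TRUE, qc = quality_thresholds(),
                         ani_primary = 0.90, ani_secondary = 0.98,
                         min_containment = 0.10, k = 21, s = 1000,
                         sketch_seed = 42, run_derep = TRUE,
                         include_undetected = TRUE) {
  need <- c("bins.tsv", "qc.tsv", "samples.tsv", "contigs.tsv",
            "genomes.fasta", "gh18.faa", "seq2bin.tsv")
  for (f in need) {
    if (!file.exists(file.path(input_dir, f))) {
      stop("input: required file '", f, "' not found in ", input_dir,
           call. = FALSE)
    }
  }
  if (!dir.exists(file.path(input_dir, "depth"))) {
    stop("input: depth/ directory not found in ", input_dir, call. = FALSE)
  }

  contig_lengths <- .stage("input",
    read_contig_lengths(file.path(input_dir, "contigs.tsv")))
  tabs <- .stage("input", read_tables(file.path(input_dir, "bins.tsv"),
                                      file.path(input_dir, "qc.tsv"),
                                      file.path(input_dir, "samples.tsv"),
                                      contig_lengths))
  bins <- tabs$bins
  meta <- tabs$samples

  selected <- .stage("qc-filter", select_high_quality(bins, qc))

  clusters <- NULL
  if (run_derep) {
    fa <- .stage("derep", read_fasta(file.path(input_dir, "genomes.fasta")))
    contig_seq <- setNames(fa$sequence, fa$id)
    genomes <- lapply(setNames(selected$contig_ids, selected$bin_id),
                      function(ids) unname(contig_seq[ids]))
    clusters <- .stage("derep",
      dereplicate(selected, genomes, ani_primary = ani_primary,
                  ani_secondary = ani_secondary,
                  min_containment = min_containment, k = k, s = s,
                  seed = sketch_seed))
    bins_final <- selected[selected$bin_id %in% clusters$representatives, ,
                           drop = FALSE]
  } else {
    bins_final <- selected
  }

  depth_files <- sort(list.files(file.path(input_dir, "depth"),
                                 full.names = TRUE))
  profiles <- .stage("detect", lapply(depth_files, read_depth_bed,
                                      contig_lengths = contig_lengths))
  names(profiles) <- vapply(profiles, function(p) p$sample_id, character(1))
  unknown <- setdiff(names(profiles), meta$sample_id)
  if (length(unknown) > 0L) {
    stop("detect: depth file for unknown sample '", unknown[1L], "'",
         call. = FALSE)
  }
  dm <- .stage("detect", detection_matrix(profiles, bins_final,
                                          contig_lengths))
  pm <- .stage("detect", call_presence(dm, threshold = threshold,
                                       strict = strict))

  gh18_fa <- .stage("chitinase",
    read_fasta(file.path(input_dir, "gh18.faa")))
  seq2bin <- .stage("chitinase",
    read.delim(file.path(input_dir, "seq2bin.tsv"),
               stringsAsFactors = FALSE))
  gh18 <- .stage("chitinase", screen_proteins(gh18_fa, seq2bin))
  # records for bins dropped by QC or dereplication are out of scope
  gh18_kept <- gh18[gh18$bin_id %in% bins_final$bin_id, , drop = FALSE]
  chit <- .stage("chitinase",
    classify_chitinolytic(gh18_kept, bins_final$bin_id))

  report <- .stage("share",
    summarize_sharing(pm, bins_final, meta,
                      include_undetected = include_undetected))
  report <- .stage("share",
    overlay_chitinolytic(report, chit$chitinolytic_bins))
  soil_overlap <- .stage("share", withCallingHandlers(
    environmental_overlap(pm, meta),
    warning = function(w) invokeRestart("muffleWarning")))

  manifest <- list(
    package = "chitimag",
    version = as.character(packageVersion("chitimag")),
    input_dir = input_dir,
    parameters = list(threshold = threshold, strict = strict,
                      min_completeness = qc$min_completeness,
                      max_redundancy = qc$max_redundancy,
                      min_bin_len = qc$min_bin_len,
                      ani_primary = ani_primary,
                      ani_secondary = ani_secondary,
                      min_containment = min_containment,
                      k = k, s = s, sketch_seed = sketch_seed,
                      run_derep = run_derep,
                      include_undetected = include_undetected),
    n_input_bins = nrow(bins),
    n_selected = nrow(selected),
    n_dereplicated = nrow(bins_final),
    samples = meta$sample_id
  )

  result <- list(selected = selected, clusters = clusters,
                 bins_final = bins_final, dm = dm, pm = pm,
                 report = report, gh18 = gh18_kept, chitinolytic = chit,
                 soil_overlap = soil_overlap, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  sel <- res$selected
  sel$contig_ids <- NULL
  tsv(sel, "selected_bins.tsv")
  if (!is.null(res$clusters)) tsv(res$clusters$clusters, "clusters.tsv")
  write_matrix_tsv(round(res$dm$detection, 6), file.path(out_dir, "detection.tsv"))
  write_matrix_tsv(round(res$dm$mean_coverage, 6), file.path(out_dir, "coverage.tsv"))
  write_matrix_tsv(res$pm$present * 1L, file.path(out_dir, "presence.tsv"))
  gh <- res$gh18
  gh$motif_hits <- vapply(gh$motif_hits, paste, character(1), collapse = ",")
  tsv(gh, "gh18_report.tsv")
  writeLines(res$chitinolytic$chitinolytic_bins,
             file.path(out_dir, "chitinolytic_bins.txt"))
  writeLines(res$soil_overlap, file.path(out_dir, "soil_overlap_bins.txt"))
  r <- res$report
  scalars <- data.frame(
    metric = c("n_bins", "n_undetected", "mean_detected_per_sample",
               "mean_samples_per_bin", "n_shared_beyond_source",
               "n_single_sample", "mean_species_per_bin",
               "n_species_specific", "n_multi_species",
               "mean_orders_per_bin", "n_single_order", "n_multi_order",
               "n_chitinolytic", "n_soil_overlap"),
    value = c(r$n_bins, r$n_undetected,
              sprintf("%.6f", r$mean_detected_per_sample),
              sprintf("%.6f", r$mean_samples_per_bin),
              r$n_shared_beyond_source, r$n_single_sample,
              sprintf("%.6f", r$mean_species_per_bin),
              r$n_species_specific, r$n_multi_species,
              sprintf("%.6f", r$mean_orders_per_bin),
              r$n_single_order, r$n_multi_order,
              r$chitinolytic_overlay$n_chitinolytic,
              length(res$soil_overlap)),
    stringsAsFactors = FALSE
  )
  tsv(scalars, "sharing_report.tsv")
  json <- list(
    threshold = r$threshold, strict = r$strict,
    n_bins = r$n_bins, n_undetected = r$n_undetected,
    mean_detected_per_sample = r$mean_detected_per_sample,
    per_sample_detected = as.list(r$per_sample_detected),
    mean_samples_per_bin = r$mean_samples_per_bin,
    n_shared_beyond_source = r$n_shared_beyond_source,
    n_single_sample = r$n_single_sample,
    mean_species_per_bin = r$mean_species_per_bin,
    n_species_specific = r$n_species_specific,
    n_multi_species = r$n_multi_species,
    mean_orders_per_bin = r$mean_orders_per_bin,
    n_single_order = r$n_single_order,
    n_multi_order = r$n_multi_order,
    chitinolytic_overlay = list(
      n_chitinolytic = r$chitinolytic_overlay$n_chitinolytic,
      counts = r$chitinolytic_overlay$counts,
      per_species = as.list(r$chitinolytic_overlay$per_species)),
    soil_overlap_bins = res$soil_overlap
  )
  jsonlite::write_json(json, file.path(out_dir, "sharing_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
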