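# hand-built 4 bins x 4 samples toy (2 species x 2 samples):
#   b1: only its source s1           -> single-sample, species-specific
#   b2: s1 (source), s2, s3          -> shared, multi-species, multi-order
#   b3: nowhere                      -> undetected
#   b4: s2 only (source is s4)       -> shared, single-sample, species-specific
toy_fixture <- function() {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    host_species = c("spA", "spA", "spB", "spB"),
    host_order = c("ordA", "ordA", "ordB", "ordB"),
    sample_type = "fecal", stringsAsFactors = FALSE)
  bins <- data.frame(bin_id = c("b1", "b2", "b3", "b4"),
                     source_sample = c("s1", "s1", "s3", "s4"),
                     stringsAsFactors = FALSE)
  det <- matrix(0, 4, 4, dimnames = list(bins$bin_id, meta$sample_id))
  det["b1", "s1"] <- 0.9
  det["b2", c("s1", "s2", "s3")] <- c(0.8, 0.5, 0.3)
  det["b4", "s2"] <- 0.6
  list(meta = meta, bins = bins, pm = call_presence(det, 0.25))
}

test_that("the toy community matches exhaustive manual enumeration", {
  fx <- toy_fixture()
  r <- summarize_sharing(fx$pm, fx$bins, fx$meta)
  expect_equal(r$n_bins, 4)
  expect_equal(r$n_undetected, 1)
  expect_equal(r$n_shared_beyond_source, 2)
  expect_equal(r$n_single_sample, 2)
  expect_equal(r$n_species_specific, 2)
  expect_equal(r$n_multi_species, 1)
  expect_equal(r$n_single_order, 2)
  expect_equal(r$n_multi_order, 1)
  expect_equal(r$mean_samples_per_bin, 1.25)
  expect_equal(r$mean_species_per_bin, 1)
  expect_equal(r$mean_orders_per_bin, 1)
  expect_equal(r$mean_detected_per_sample, 1.25)
  expect_equal(unname(r$samples_per_bin), c(1L, 3L, 0L, 1L))
  # partition identities
  expect_equal(r$n_single_sample + sum(r$samples_per_bin >= 2) +
                 r$n_undetected, r$n_bins)
  expect_equal(r$n_species_specific + r$n_multi_species + r$n_undetected,
               r$n_bins)
  expect_equal(r$n_single_order + r$n_multi_order + r$n_undetected, r$n_bins)
})

test_that("a bin present only in its source sample is not shared", {
  fx <- toy_fixture()
  det <- matrix(0, 1, 4, dimnames = list("b1", fx$meta$sample_id))
  det["b1", "s1"] <- 0.9
  bins <- data.frame(bin_id = "b1", source_sample = "s1",
                     stringsAsFactors = FALSE)
  r <- summarize_sharing(call_presence(det, 0.25), bins, fx$meta)
  expect_equal(r$n_shared_beyond_source, 0)
  expect_equal(r$n_single_sample, 1)
  expect_equal(unname(r$species_per_bin), 1L)
})

test_that("sharing categories equal set-arithmetic enumeration on random fixtures", {
  set.seed(61)
  for (rep in 1:200) {
    fx <- random_presence_fixture(n_bins = sample(4:15, 1),
                                  n_species = sample(2:4, 1))
    pm <- call_presence(fx$detection, 0.25)
    r <- summarize_sharing(pm, fx$bins, fx$meta)
    fec <- fx$meta[fx$meta$sample_type == "fecal", ]
    present <- pm$present[, fec$sample_id, drop = FALSE]
    o <- oracle_sharing(present,
                        setNames(fx$bins$source_sample, fx$bins$bin_id),
                        setNames(fec$host_species, fec$sample_id),
                        setNames(fec$host_order, fec$sample_id))
    for (f in c("n_undetected", "n_single_sample", "n_shared_beyond_source",
                "n_species_specific", "n_multi_species", "n_single_order",
                "n_multi_order", "mean_samples_per_bin",
                "mean_species_per_bin", "mean_orders_per_bin")) {
      expect_equal(r[[f]], o[[f]], info = f)
    }
    # partition identities hold on every fixture
    expect_equal(r$n_single_sample + sum(r$samples_per_bin >= 2) +
                   r$n_undetected, r$n_bins)
    expect_equal(r$n_species_specific + r$n_multi_species + r$n_undetected,
                 r$n_bins)
    expect_equal(r$n_single_order + r$n_multi_order + r$n_undetected,
                 r$n_bins)
  }
})

test_that("the report is invariant to permuting matrix rows and columns", {
  set.seed(62)
  fx <- random_presence_fixture(n_bins = 10)
  pm1 <- call_presence(fx$detection, 0.25)
  perm <- fx$detection[sample(rownames(fx$detection)),
                       sample(colnames(fx$detection))]
  pm2 <- call_presence(perm, 0.25)
  r1 <- summarize_sharing(pm1, fx$bins, fx$meta)
  r2 <- summarize_sharing(pm2, fx$bins, fx$meta)
  for (f in c("n_undetected", "n_single_sample", "n_shared_beyond_source",
              "n_species_specific", "n_multi_species",
              "mean_samples_per_bin", "mean_species_per_bin")) {
    expect_equal(r1[[f]], r2[[f]], info = f)
  }
  expect_equal(r1$samples_per_bin[sort(names(r1$samples_per_bin))],
               r2$samples_per_bin[sort(names(r2$samples_per_bin))])
})

test_that("restricting the sample set never increases samples_per_bin", {
  set.seed(63)
  fx <- random_presence_fixture(n_bins = 10, n_species = 3)
  pm_full <- call_presence(fx$detection, 0.25)
  keep <- fx$meta$sample_id[-2]
  # keep each bin's source sample so the report remains computable
  keep <- union(keep, fx$bins$source_sample)
  pm_sub <- call_presence(fx$detection[, keep, drop = FALSE], 0.25)
  r_full <- summarize_sharing(pm_full, fx$bins, fx$meta)
  r_sub <- summarize_sharing(pm_sub, fx$bins,
                             fx$meta[fx$meta$sample_id %in% keep, ])
  expect_true(all(r_sub$samples_per_bin <= r_full$samples_per_bin))
})

test_that("a source sample missing from the matrix is an error", {
  fx <- toy_fixture()
  det <- matrix(0.5, 4, 3,
                dimnames = list(fx$bins$bin_id, c("s1", "s2", "s3")))
  expect_error(summarize_sharing(call_presence(det, 0.25), fx$bins,
                                 fx$meta), "source sample 's4'")
})

test_that("environmental overlap applies the threshold rule to soil columns", {
  meta <- data.frame(sample_id = c("f1", "soil1", "soil2"),
                     host_species = c("spA", "", ""),
                     host_order = c("ordA", "", ""),
                     sample_type = c("fecal", "soil", "soil"),
                     stringsAsFactors = FALSE)
  det <- matrix(c(0.9, 0.9, 0.9,   # f1
                  0.30, 0.25, 0.0, # soil1
                  0.0, 0.0, 0.0),  # soil2
                nrow = 3,
                dimnames = list(c("b1", "b2", "b3"),
                                c("f1", "soil1", "soil2")))
  pm <- call_presence(det, 0.25, strict = TRUE)
  expect_equal(environmental_overlap(pm, meta), "b1")  # 0.25 excluded by '>'
  pm2 <- call_presence(det, 0.25, strict = FALSE)
  expect_equal(environmental_overlap(pm2, meta), c("b1", "b2"))
  expect_equal(environmental_overlap(pm, meta, bin_subset = "b2"),
               character(0))
})

test_that("environmental overlap equals a brute-force scan on random fixtures", {
  set.seed(64)
  for (rep in 1:20) {
    fx <- random_presence_fixture(n_bins = 8, n_soil = 3)
    pm <- call_presence(fx$detection, 0.25)
    soil_ids <- fx$meta$sample_id[fx$meta$sample_type == "soil"]
    want <- sort(Filter(function(b) any(fx$detection[b, soil_ids] > 0.25),
                        rownames(fx$detection)))
    expect_equal(environmental_overlap(pm, fx$meta), want)
  }
})

test_that("overlap without soil samples warns and returns empty", {
  fx <- toy_fixture()
  expect_warning(out <- environmental_overlap(fx$pm, fx$meta), "no soil")
  expect_equal(out, character(0))
})

test_that("chitinolytic overlay splits every category consistently", {
  fx <- toy_fixture()
  r <- summarize_sharing(fx$pm, fx$bins, fx$meta)
  none <- overlay_chitinolytic(r, character(0))
  expect_true(all(none$chitinolytic_overlay$counts$chitinolytic == 0))
  all_bins <- overlay_chitinolytic(r, fx$bins$bin_id)
  cnt <- all_bins$chitinolytic_overlay$counts
  expect_true(all(cnt$other == 0))
  expect_equal(cnt["shared_beyond_source", "chitinolytic"],
               r$n_shared_beyond_source)
  expect_equal(cnt["species_specific", "chitinolytic"], r$n_species_specific)
  some <- overlay_chitinolytic(r, c("b2", "b4"))
  expect_equal(some$chitinolytic_overlay$counts["shared_beyond_source", ],
               data.frame(chitinolytic = 2L, other = 0L,
                          row.names = "shared_beyond_source"))
  expect_equal(unname(some$chitinolytic_overlay$per_species["spA"]), 2)
  expect_error(overlay_chitinolytic(r, "nope"), "unknown bin id")
})
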