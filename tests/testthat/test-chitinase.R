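test_that("the active-site motif matches its anchors exactly", {
  expect_equal(scan_active_site("DAADADAE"), 1L)
  expect_equal(scan_active_site("DAADADAD"), integer(0)) # no terminal E
  expect_equal(scan_active_site("daadadae"), 1L)         # case-insensitive
  expect_equal(scan_active_site(""), integer(0))
  # wildcards accept anything, anchors reject ambiguity codes
  expect_equal(scan_active_site("DAXDXDXE"), 1L)
  expect_equal(scan_active_site("XAADADAE"), integer(0))
  # gaps are removed before scanning by default, counted as mismatch if not
  expect_equal(scan_active_site("D-AAD-ADAE"), 1L)
  expect_equal(scan_active_site("D-AADADAE", degap = FALSE), integer(0))
})

test_that("overlapping motif hits are all reported", {
  # two interleaved matches at offsets 1 and 2: DxxDxDxE over DDADDDDEE
  s <- "DDADDDDEE"
  expect_equal(scan_active_site(s), oracle_motif_scan(s))
  expect_equal(length(scan_active_site(s)), 2L)
})

test_that("motif scan equals the sliding-window oracle on 1000 random proteins", {
  set.seed(71)
  motif <- gh18_motif()
  for (i in 1:1000) {
    p <- random_protein(200)
    expect_identical(scan_active_site(p, motif), oracle_motif_scan(p))
  }
})

test_that("self-concatenation at least doubles the motif hits", {
  set.seed(72)
  for (i in 1:50) {
    p <- random_protein(60)
    # plant one motif so most sequences have something to double
    pos <- sample(1:52, 1)
    substr(p, pos, pos + 7) <- "DQQDQDQE"
    doubled <- paste0(p, p)
    h1 <- scan_active_site(p)
    h2 <- scan_active_site(doubled)
    expect_gte(length(h2), 2L * length(h1))
    expect_identical(h2, oracle_motif_scan(doubled))
  }
})

test_that("alignment masking keeps columns at exactly the occupancy cutoff", {
  aln <- c(a = "A-CD", b = "A-CD", c = "A--D", d = "A--D")
  # occupancies: 1, 0, 0.5, 1
  m <- mask_alignment(aln, 0.5)
  expect_equal(m$kept_columns, c(1L, 3L, 4L))
  expect_equal(unname(m$sequences["a"]), "ACD")
  all_gap <- c(a = "A-", b = "C-")
  expect_equal(mask_alignment(all_gap, 0.5)$kept_columns, 1L)
})

test_that("masking is identity at occupancy 0 and empty above 1", {
  aln <- c(a = "AC-D", b = "-CGD")
  expect_equal(mask_alignment(aln, 0)$sequences,
               setNames(aln, names(aln)))
  m <- mask_alignment(aln, 1.5)
  expect_equal(length(m$kept_columns), 0L)
  expect_equal(unname(m$sequences), c("", ""))
  expect_error(mask_alignment(c(a = "ACD", b = "AC")), "ragged")
})

test_that("masking equals a column-wise brute force on random alignments", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 20; w <- 100
    m <- matrix(sample(c("A", "C", "D", "-"), n * w, replace = TRUE,
                       prob = c(0.25, 0.25, 0.2, 0.3)), n, w)
    aln <- setNames(apply(m, 1, paste, collapse = ""),
                    sprintf("s%02d", 1:n))
    got <- mask_alignment(aln, 0.5)
    want <- which(vapply(seq_len(w), function(j)
      mean(m[, j] != "-") >= 0.5, logical(1)))
    expect_equal(got$kept_columns, want)
  }
})

test_that("bins are chitinolytic iff they carry an active-site record", {
  records <- data.frame(
    seq_id = c("q1", "q2", "q3"),
    bin_id = c("binA", "binA", "binB"),
    n_motif_hits = c(0L, 0L, 2L),
    active_site = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  cl <- classify_chitinolytic(records, c("binA", "binB", "binC"))
  pb <- cl$per_bin
  expect_equal(pb$n_gh18, c(2L, 1L, 0L))
  expect_equal(pb$n_active, c(0L, 1L, 0L))
  expect_equal(cl$chitinolytic_bins, "binB")
  expect_error(classify_chitinolytic(records, "binA"), "unknown bin")
  # |chitinolytic| <= |bins with GH18| <= |bins|
  expect_lte(length(cl$chitinolytic_bins), sum(pb$n_gh18 > 0))
  expect_lte(sum(pb$n_gh18 > 0), nrow(pb))
})

test_that("screen_proteins links records to bins and flags active sites", {
  prots <- data.frame(id = c("p1", "p2"),
                      sequence = c("MMDAADADAEMM", "MMMM"),
                      stringsAsFactors = FALSE)
  s2b <- data.frame(seq_id = c("p1", "p2"), bin_id = c("b1", "b2"),
                    stringsAsFactors = FALSE)
  recs <- screen_proteins(prots, s2b)
  expect_equal(recs$active_site, c(TRUE, FALSE))
  expect_equal(recs$motif_hits[[1]], 3L)
  expect_error(screen_proteins(prots, s2b[1, , drop = FALSE]),
               "no bin mapping")
})

test_that("the planted chitinolytic fraction is recovered across seeds", {
  # generator plants active sites in ~62% of GH18-carrying bins; over 30
  # seeds the recovered fraction must sit inside a 99.9% binomial envelope
  n_gh18_total <- 0
  n_chit_total <- 0
  for (seed in 1:30) {
    spec <- community_spec(seed = seed, n_bins = 30, n_lowq = 0,
                           genome_len = 500, contigs_per_bin = 1)
    b <- generate_community(spec)
    recs <- screen_proteins(b$proteins, b$seq2bin)
    cl <- classify_chitinolytic(recs, b$bins$bin_id)
    expect_setequal(cl$chitinolytic_bins, b$truth$chitinolytic_bins)
    n_gh18_total <- n_gh18_total + sum(cl$per_bin$n_gh18 > 0)
    n_chit_total <- n_chit_total + length(cl$chitinolytic_bins)
  }
  phat <- n_chit_total / n_gh18_total
  se <- sqrt(0.62 * 0.38 / n_gh18_total)
  expect_lt(abs(phat - 0.62), 3.3 * se)
})
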