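test_that("contig breadth handles simple, overlapping and empty interval sets", {
  p <- depth_profile(data.frame(contig = "c1", start = 0, end = 250, depth = 1),
                     "s1")
  cb <- contig_breadth(p, "c1", 1000)
  expect_equal(cb$covered_bp, 250L)
  expect_equal(cb$mean_depth, 0.25)

  p2 <- depth_profile(data.frame(contig = "c1", start = c(0, 50),
                                 end = c(100, 150), depth = c(1, 2)), "s1")
  cb2 <- contig_breadth(p2, "c1", 200)
  expect_equal(cb2$covered_bp, 150L) # union of overlapping intervals
  expect_equal(cb2$mean_depth, (100 + 200) / 200)

  p3 <- depth_profile(data.frame(contig = character(), start = integer(),
                                 end = integer(), depth = integer()), "s1")
  cb3 <- contig_breadth(p3, "c1", 500)
  expect_equal(cb3$covered_bp, 0L)
  expect_equal(cb3$mean_depth, 0)

  expect_error(contig_breadth(p, "c1", 100), "beyond contig")
})

test_that("bin detection is the covered fraction of the bin length", {
  iv <- data.frame(contig = c("c1", "c2"), start = c(0, 0),
                   end = c(300, 100), depth = c(2, 1))
  p <- depth_profile(iv, "s1")
  bd <- bin_detection(p, c("c1", "c2"), c(c1 = 600L, c2 = 400L))
  expect_equal(bd$detection, 0.4)
  expect_error(bin_detection(p, c("c1", "cX"), c(c1 = 600L)), "'cX'")

  full <- depth_profile(data.frame(contig = c("c1", "c2"), start = c(0, 0),
                                   end = c(600, 400), depth = 1), "s1")
  expect_equal(bin_detection(full, c("c1", "c2"),
                             c(c1 = 600L, c2 = 400L))$detection, 1)
})

test_that("detection and mean coverage equal a per-position oracle on 50 random fixtures", {
  set.seed(51)
  for (rep in 1:50) {
    fx <- random_depth_fixture()
    p <- depth_profile(fx$intervals, "s1", fx$contig_lengths)
    cids <- names(fx$contig_lengths)
    got <- bin_detection(p, cids, fx$contig_lengths)
    want <- oracle_bin_detection(fx$intervals, fx$contig_lengths, cids)
    expect_equal(got$detection, want$detection)
    expect_equal(got$mean_coverage, want$mean_coverage)
    # matrix path agrees with the scalar path
    bins <- data.frame(bin_id = "b1", stringsAsFactors = FALSE)
    bins$contig_ids <- list(cids)
    dm <- detection_matrix(list(s1 = p), bins, fx$contig_lengths)
    expect_equal(unname(dm$detection["b1", "s1"]), want$detection)
    expect_equal(unname(dm$mean_coverage["b1", "s1"]), want$mean_coverage)
  }
})

test_that("detection is invariant to splitting intervals at equal depth", {
  whole <- depth_profile(data.frame(contig = "c1", start = 10, end = 90,
                                    depth = 3), "s1")
  split3 <- depth_profile(data.frame(contig = "c1", start = c(10, 40, 70),
                                     end = c(40, 70, 90), depth = 3), "s1")
  a <- contig_breadth(whole, "c1", 100)
  b <- contig_breadth(split3, "c1", 100)
  expect_equal(a, b)
})

test_that("presence calls respect boundary strictness and match an elementwise oracle", {
  det <- matrix(c(0.25, 0.2501, 0, 1), 2, 2,
                dimnames = list(c("b1", "b2"), c("s1", "s2")))
  strict <- call_presence(det, 0.25, strict = TRUE)
  loose <- call_presence(det, 0.25, strict = FALSE)
  expect_false(strict$present["b1", "s1"]) # exactly at threshold
  expect_true(loose$present["b1", "s1"])
  expect_true(strict$present["b2", "s1"])

  set.seed(52)
  m <- matrix(runif(200), 20, 10,
              dimnames = list(sprintf("b%d", 1:20), sprintf("s%d", 1:10)))
  pm <- call_presence(m, 0.25)
  expect_equal(pm$present, m > 0.25)
  expect_error(call_presence(m * 2), "\\[0, 1\\]")
})

test_that("raising the threshold never adds presences", {
  set.seed(53)
  m <- matrix(runif(300), 30, 10,
              dimnames = list(sprintf("b%d", 1:30), sprintf("s%d", 1:10)))
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.9),
                   function(t) sum(call_presence(m, t)$present), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an all-zero detection matrix yields no presences", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_equal(sum(call_presence(m)$present), 0L)
})
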