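# TPM normalisation, island detection, unique-region masking, and gender
# fold changes.

test_that("TPM columns sum to one million and follow the closed form", {
  expect_equal(unname(tpm_normalize(matrix(5), 1234)[1, 1]), 1e6)
  # two features, equal counts, lengths L and 2L -> 2:1 split
  tpm <- tpm_normalize(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(tpm[, 1], c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # column-sum conservation on random tables
  set.seed(9)
  m <- matrix(rpois(60, 100), 10, 6)
  tpm <- tpm_normalize(m, sample(200:3000, 10))
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)
  expect_error(tpm_normalize(matrix(c(1, 0), 1, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             100), "all-zero sample")
  expect_error(tpm_normalize(matrix(1), 0), "positive")
})

test_that("islands merge adjacent windows and respect the gene mask", {
  params <- island_params(merged_count_threshold = 12000)
  w <- data.frame(molecule = "1", start = as.integer(seq(0, 2000, 100)),
                  count = 500)
  expect_equal(nrow(detect_islands(w, params = params)), 0)

  # 4 adjacent windows at 2x threshold from 0-based 371386
  w2 <- data.frame(molecule = "1",
                   start = as.integer(seq(371086, 372086, 100)),
                   count = 100)
  w2$count[w2$start %in% c(371386, 371486, 371586, 371686)] <- 24000
  isl <- detect_islands(w2, params = params)
  expect_equal(isl$name, "1.371387(400)")
  expect_equal(isl$length, 400)

  # two qualifying windows separated by one failing window -> two islands
  w3 <- data.frame(molecule = "1", start = as.integer(seq(0, 400, 100)),
                   count = c(20000, 100, 20000, 100, 100))
  expect_equal(nrow(detect_islands(w3, params = params)), 2)

  # gene-overlapping windows are masked before thresholding
  mask <- data.frame(molecule = "1", start = 371400L, end = 371500L)
  isl_m <- detect_islands(w2, mask, params)
  expect_false(any(grepl("371387", isl_m$name)))

  # every emitted island's windows meet the threshold
  set.seed(21)
  w4 <- data.frame(molecule = "1", start = as.integer(seq(0, 9900, 100)),
                   count = rpois(100, 9000))
  isl4 <- detect_islands(w4, params = params)
  for (i in seq_len(nrow(isl4))) {
    inside <- w4$count[w4$start >= isl4$start[i] &
                         w4$start < isl4$start[i] + isl4$length[i]]
    expect_true(all(inside >= 12000))
  }
})

test_that("island detection is translation-equivariant", {
  set.seed(31)
  counts <- rpois(60, 8000); counts[20:24] <- 30000
  w <- data.frame(molecule = "1", start = as.integer(seq(0, 5900, 100)),
                  count = counts)
  k <- 7L
  w_shift <- w
  w_shift$count <- c(rep(0, k), counts[seq_len(60 - k)])
  a <- detect_islands(w)
  b <- detect_islands(w_shift)
  expect_equal(b$start, a$start + 100L * k)
  expect_equal(b$length, a$length)
})

test_that("island names round-trip through the parser", {
  set.seed(22)
  for (i in 1:50) {
    mol <- as.character(sample(1:5, 1))
    start <- sample(0:500000, 1)
    len <- 100L * sample(1:30, 1)
    parsed <- parse_island_name(island_name(mol, start, len))
    expect_equal(parsed, list(molecule = mol, start = start, length = len))
  }
  expect_error(parse_island_name("nonsense"), "not an island name")
})

test_that("unique-region coverage masks repeat-shared positions", {
  depth <- rep(10, 1000)
  feat <- list(start = 100L, end = 400L)
  # no repeat overlap: plain mean
  expect_equal(unique_region_coverage(feat, NULL, depth)$mean_depth, 10)

  # chimera whose borrowed portions are masked: only the specific core counts
  depth2 <- c(rep(0, 100), rep(c(30, 50, 30), each = 100), rep(0, 600))
  repeats <- data.frame(start = c(100L, 300L), end = c(200L, 400L))
  u <- unique_region_coverage(feat, repeats, depth2)
  expect_equal(u$mean_depth, 50)  # by-hand mask: only [200, 300) remains
  expect_equal(u$n_unique, 100L)
  expect_equal(u$kept, data.frame(start = 200L, end = 300L))

  # fully masked feature is flagged, no value
  full <- unique_region_coverage(feat, data.frame(start = 0L, end = 500L),
                                 depth)
  expect_true(is.na(full$mean_depth))
  expect_equal(full$flag, "fully_masked")
})

test_that("gender fold change handles direction and zero means", {
  cov <- data.frame(feature = "f", sample = c("F1", "F2", "H1", "H2"),
                    tpm = c(30, 30, 30, 30))
  sheet <- data.frame(sample = c("F1", "F2", "H1", "H2"),
                      gender = c("F", "F", "H", "H"))
  expect_equal(gender_fold_change(cov, sheet, "f")$ratio, 1)

  cov$tpm <- c(0, 0, 10, 30)
  fc <- gender_fold_change(cov, sheet, "f")
  expect_lt(fc$ratio, 1)
  expect_false(fc$pseudo_count)

  cov$tpm <- c(10, 30, 0, 0)
  fc2 <- gender_fold_change(cov, sheet, "f")
  expect_true(fc2$pseudo_count)
  expect_gt(fc2$ratio, 1)

  expect_error(gender_fold_change(cov[1:2, ], sheet[1:2, ], "f"),
               "both genders")
})

test_that("a planted 3-fold gender effect is recovered within 10% (median of 200 runs)", {
  panel <- toy_expression_panel()
  ratios <- vapply(seq_len(200), function(s) {
    sim <- simulate_coverage(panel, seed = s)
    tpm <- tpm_normalize(sim$counts, panel$length)
    long <- data.frame(feature = rep(rownames(tpm), ncol(tpm)),
                       sample = rep(colnames(tpm), each = nrow(tpm)),
                       tpm = as.vector(tpm))
    gender_fold_change(long, sim$samples, "bobt")$ratio
  }, 0)
  expect_lt(abs(stats::median(ratios) - 3) / 3, 0.10)
})
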