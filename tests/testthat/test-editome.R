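# Editome comparison: classification of homologous site pairs, summary
# counts, symmetry, and rate correlation.

test_that("the packaged KRA/KOV difference table classifies row-for-row", {
  map <- kra_kov_sites()
  cmp <- compare_editomes(map)
  expected <- c(loss = "loss_substitution", new = "new_editing",
                large = "highly_differential")
  expect_equal(cmp$class, unname(expected[map$section]))
  # every mapped row receives exactly one class
  expect_true(all(cmp$class %in% c("conserved_edited", "conserved_unedited",
                                   "loss_substitution", "loss_activity",
                                   "new_editing", "highly_differential",
                                   "minor_difference", "unalignable")))
})

test_that("summary counts reproduce the between-haplotype differences", {
  cmp <- compare_editomes(kra_kov_sites())
  s <- summarize_comparison(cmp)
  expect_equal(unname(s$by_class["highly_differential"]), 4L)
  expect_equal(unname(s$by_class["new_editing"]), 4L)
  expect_equal(unname(s$by_class["loss_substitution"]), 4L)
  # restricted to intact protein-coding genes, 3 losses remain (the
  # chimeric-ORF partial gene is reported separately)
  expect_equal(s$losses, 3L)
  # 3 of the 4 highly differential sites sit in mttB
  hd <- cmp[cmp$class == "highly_differential", ]
  expect_equal(sum(hd$gene == "mttB"), 3L)
  # codon annotation: 3 of 4 highly differential sites are non-synonymous
  expect_equal(sum(!hd$synonymous), 3L)
  # empty input gives an all-zero summary
  s0 <- summarize_comparison(compare_editomes(kra_kov_sites()[0, ]))
  expect_true(all(s0$by_class == 0))
  expect_equal(s0$losses, 0L)
})

test_that("single site pairs classify per the decision order", {
  th <- comparison_thresholds()
  expect_equal(as.character(classify_site_pair("T", "C", NA, 0.97, th)),
               "loss_substitution")
  expect_equal(as.character(classify_site_pair("C", "C", 0.14, NA, th)),
               "new_editing")
  expect_equal(as.character(classify_site_pair("C", "C", 0.87, 0.09, th)),
               "highly_differential")
  # measured silence against a strong edit is an activity loss
  expect_equal(as.character(classify_site_pair("C", "C", 0.9, 0.0005, th)),
               "loss_activity")
  # strict bounds: 0.8 / 0.3 exactly is not highly differential
  expect_equal(as.character(classify_site_pair("C", "C", 0.8, 0.3, th)),
               "conserved_edited")
  expect_equal(as.character(classify_site_pair("C", "C", 0.95, 0.9, th)),
               "conserved_edited")
  expect_equal(as.character(classify_site_pair("C", "C", 0.05, NA, th)),
               "conserved_unedited")
  expect_equal(as.character(classify_site_pair("C", "C", 0.5, 0.05, th)),
               "minor_difference")
  expect_equal(as.character(classify_site_pair("A", "C", NA, 0.9, th)),
               "unalignable")
  # a T/C pair without editing on the C side is not a loss
  expect_equal(as.character(classify_site_pair("T", "C", NA, NA, th)),
               "conserved_unedited")
})

test_that("swapping haplotypes maps classes symmetrically", {
  map <- kra_kov_sites()
  fwd <- compare_editomes(map)
  swapped <- map
  names(swapped)[match(c("ref_a", "ref_b", "rate_a", "rate_b",
                         "position_a", "position_b"), names(swapped))] <-
    c("ref_b", "ref_a", "rate_b", "rate_a", "position_b", "position_a")
  rev <- compare_editomes(swapped)
  expect_equal(rev$class, fwd$class)
  # direction flips where it is meaningful
  flip <- c(a = "b", b = "a", a_high = "b_high", b_high = "a_high")
  has_dir <- !is.na(fwd$direction)
  expect_equal(rev$direction[has_dir], unname(flip[fwd$direction[has_dir]]))
})

test_that("rate correlation behaves at the extremes and under noise", {
  base <- data.frame(gene = "g", ref_a = "C", ref_b = "C",
                     rate_a = c(0.1, 0.5, 0.9, 0.3, 0.7))
  ident <- base; ident$rate_b <- ident$rate_a
  r <- rate_correlation(ident)
  expect_equal(r$spearman, 1)
  expect_equal(r$pearson, 1)
  anti <- base; anti$rate_b <- 1 - anti$rate_a
  expect_equal(rate_correlation(anti)$spearman, -1)

  set.seed(77)
  sim <- data.frame(gene = "g", ref_a = "C", ref_b = "C",
                    rate_a = runif(500))
  sim$rate_b <- pmin(1, pmax(0, sim$rate_a + rnorm(500, 0, 0.05)))
  expect_gt(rate_correlation(sim)$spearman, 0.9)

  expect_error(rate_correlation(base[1:2, ]), "fewer than 3")
})
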