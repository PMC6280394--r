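# Editing extent, site calling thresholds, strand orientation, context
# precedence, and codon-effect annotation.

test_that("editing extent is T/(C+T) and ignores other bases", {
  expect_equal(editing_extent(3, 97), 0.97)
  expect_equal(editing_extent(50, 0), 0)
  expect_equal(editing_extent(0, 80), 1)
  expect_warning(out <- editing_extent(0, 0), "zero usable")
  expect_true(is.na(out))
  # monotone in t at fixed c
  t <- 0:50
  expect_true(all(diff(editing_extent(rep(20, 51), t)) > 0))
})

test_that("site calling requires ref C, 10% extent and 10 edited reads", {
  p <- data.frame(molecule = "1", pos = 0:3, strand = "+",
                  ref = c("C", "C", "T", "C"),
                  nA = 0L, nG = 0L,
                  nC = c(90L, 91L, 0L, 5L),
                  nT = c(10L, 9L, 100L, 95L))
  calls <- call_editing_sites(p)
  # boundary: exactly 10% and exactly 10 reads is called
  expect_true(calls$called[1])
  # 9% and 9 reads fails both prongs
  expect_false(calls$called[2])
  # a genomic T is a substitution, never an editing site
  expect_false(calls$called[3])
  expect_true(calls$called[4])
  # audit: every candidate is retained
  expect_equal(nrow(calls), 4)
  # low-depth flag at C+T < 10
  p2 <- data.frame(molecule = "1", pos = 0L, strand = "+", ref = "C",
                   nA = 0L, nG = 0L, nC = 4L, nT = 5L)
  expect_true(call_editing_sites(p2)$low_depth)
})

test_that("minus-strand counts re-orient so editing logic sees C>T", {
  # genomic G>A on the plus strand is C>T on the minus strand of interest
  p <- data.frame(molecule = "1", pos = 10L, ref = "G", strand = "-",
                  nA = 40L, nC = 0L, nG = 60L, nT = 0L)
  o <- orient_pileup(p)
  expect_equal(o$ref, "C")
  expect_equal(o$nC, 60L)
  expect_equal(o$nT, 40L)
  expect_true(call_editing_sites(o)$called)
  # plus-strand rows are untouched
  q <- data.frame(molecule = "1", pos = 2L, ref = "C", strand = "+",
                  nA = 1L, nC = 7L, nG = 2L, nT = 13L)
  expect_identical(orient_pileup(q), q)
})

test_that("rRNA/tRNA positions are excluded from calling", {
  feats <- data.frame(feature_id = "rrn18", molecule = "1",
                      start = 0L, end = 100L, strand = "+", kind = "rRNA")
  p <- data.frame(molecule = "1", pos = c(50L, 150L), ref = "C",
                  strand = "+", nA = 0L, nG = 0L, nC = 50L, nT = 50L)
  calls <- call_editing_sites(p, features = feats)
  expect_false(calls$called[1])
  expect_true(calls$called[2])
})

test_that("context classification follows CDS > intron > UTR > ORF > island", {
  feats <- data.frame(
    feature_id = c("cds1", "orf1", "int1", "utr1", "isl1"),
    molecule = "1",
    start = c(100L, 100L, 300L, 300L, 500L),
    end = c(200L, 250L, 400L, 400L, 600L),
    strand = c("+", "+", "+", "+", "+"),
    kind = c("CDS", "ORF", "intron", "UTR", "island"))
  expect_equal(classify_context(150, feats, "1"), "CDS")
  expect_equal(classify_context(220, feats, "1"), "ORF")
  expect_equal(classify_context(350, feats, "1"), "intron")
  expect_equal(classify_context(550, feats, "1", strand = "-"), "island")
  expect_equal(classify_context(900, feats, "1"), "intergenic")
  # stranded kinds must match the query strand
  expect_equal(classify_context(150, feats, "1", strand = "-"), "intergenic")
})

test_that("codon effects match known editing outcomes", {
  # serine -> leucine at codon position 2
  e <- annotate_effect("ATGTCATAA", 4)
  expect_equal(e$codon_before, "TCA")
  expect_equal(e$codon_after, "TTA")
  expect_equal(c(e$aa_before, e$aa_after), c("S", "L"))
  expect_false(e$synonymous)
  expect_equal(e$codon_position, 2)
  # leucine -> leucine at codon position 1 is silent
  e2 <- annotate_effect("CTGAAA", 0)
  expect_equal(c(e2$codon_before, e2$codon_after), c("CTG", "TTG"))
  expect_true(e2$synonymous)
  # threonine third-position edit is silent
  e3 <- annotate_effect("ACCGGG", 2)
  expect_equal(c(e3$codon_before, e3$codon_after), c("ACC", "ACT"))
  expect_true(e3$synonymous)
  expect_error(annotate_effect("ACCG", 0, "genX"), "multiple of 3")
  expect_error(annotate_effect("ATGAAA", 3), "not a C")
})

test_that("annotate_effect agrees with translating the whole mutated CDS", {
  set.seed(60)
  for (i in 1:20) {
    n_codons <- sample(5:30, 1)
    cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"),
                                      3 * n_codons, replace = TRUE),
                               collapse = ""))
    c_pos <- which(strsplit(cds, "")[[1]] == "C")
    if (!length(c_pos)) next
    pos <- sample(c_pos, 1) - 1L
    e <- annotate_effect(cds, pos)
    mutated <- cds
    substr(mutated, pos + 1, pos + 1) <- "T"
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE))
    aa_mut <- as.character(Biostrings::translate(
      Biostrings::DNAString(mutated), no.init.codon = TRUE))
    expect_equal(e$synonymous, aa_ref == aa_mut)
    idx <- pos %/% 3 + 1
    expect_equal(e$aa_before, substr(aa_ref, idx, idx))
    expect_equal(e$aa_after, substr(aa_mut, idx, idx))
  }
})

test_that("simulated binomial pileups recover true rates within 2 binomial SDs", {
  for (n in c(50, 200, 1000)) {
    p <- 0.35
    pil <- simulate_pileup(rep(p, 1000), n, seed = 1000 + n)
    calls <- call_editing_sites(orient_pileup(pil))
    mae <- mean(abs(calls$extent - p))
    expect_lt(mae, 2 * sqrt(p * (1 - p) / n))
  }
})

test_that("pileup TSV round trip preserves the 1-based disk convention", {
  p <- simulate_pileup(c(0.2, 0.8), 50, seed = 5)[, 1:8]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(p, path)
  on_disk <- utils::read.delim(path)
  expect_equal(on_disk$pos, p$pos + 1L)
  expect_equal(read_pileup(path)$pos, p$pos)
})

test_that("mpileup text parsing counts bases and skips markup", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t100\tC\t8\t..,,TTt^].\tIIIIIIII",
               "chr1\t101\tG\t5\t.,+2ATa$.\tIIIII"), path)
  p <- parse_mpileup(path)
  expect_equal(p$nC[1], 5L)  # 5 reference-matching reads
  expect_equal(p$nT[1], 3L)
  expect_equal(p$pos[1], 99L)
  expect_equal(p$nG[2], 3L)
  expect_equal(p$nA[2], 1L)
})
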