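# Recombination moves, canonical forms, state enumeration, and the
# transcriptional context of genes across configurations.

test_that("canonical form quotients circles by rotation and strand flip", {
  m <- mt_molecule("m", "circular", c("B+", "A+"))
  expect_equal(layout_key(canonicalize(m)), "A+ B+")
  # a circle equals its own full strand flip
  m1 <- mt_molecule("m", "circular", c("A+", "B+"))
  m2 <- mt_molecule("m", "circular", c("B-", "A-"))
  expect_equal(layout_key(canonicalize(m1)), layout_key(canonicalize(m2)))

  set.seed(100)
  for (i in 1:200) {
    m <- random_circle(sample(2:7, 1))
    n <- nrow(m$layout)
    lay <- m$layout[((seq_len(n) - 1 + sample(n, 1)) %% n) + 1, ]
    if (runif(1) < 0.5) {
      lay <- lay[rev(seq_len(n)), ]
      lay$orientation <- ifelse(lay$orientation == "+", "-", "+")
    }
    m_t <- mt_molecule("m", "circular", lay)
    expect_equal(layout_key(canonicalize(m_t)), layout_key(canonicalize(m)))
  }
  # idempotence
  m <- random_circle(5)
  expect_equal(layout_key(canonicalize(canonicalize(m))),
               layout_key(canonicalize(m)))
})

test_that("inversion is an involution and arc choice does not matter", {
  g <- toy$genome
  c0 <- initial_config(g)
  for (pair in c("atp6", "cob")) {
    c1 <- invert_across(g, c0, pair)
    c2 <- invert_across(g, c1, pair)
    expect_equal(config_key(c2), config_key(c0))
  }
  # inverting across one pair makes the other pair direct
  c1 <- invert_across(g, c0, "atp6")
  lay <- c1$molecules[[1]]$layout
  cob_occ <- lay$orientation[lay$segment_id == "C"]
  expect_equal(cob_occ[1], cob_occ[2])
  # arc-choice independence, by brute force on random two-pair circles:
  # relabelling which copy is "first" (rotation) selects the other arc
  set.seed(200)
  for (i in 1:25) {
    segs <- data.frame(segment_id = c("R", "P", "Q", "S", "T", "U"),
                       sequence = replicate(6, strrep("ACGT", 10)))
    lay <- data.frame(
      segment_id = c("R", sample(c("P", "Q"), 1), "R",
                     sample(c("S", "T", "U"), 2)),
      orientation = c("+", "+", "-", sample(c("+", "-"), 2, replace = TRUE)))
    gg <- mt_genome(segs, list(mt_molecule("c", "circular", lay)),
                    repeat_pairs = data.frame(pair_id = "r",
                                              segment_id = "R", length = 40L,
                                              identity = 1, enabled = TRUE))
    cfg <- initial_config(gg)
    k <- sample(nrow(lay), 1)
    rot <- mt_config(list(mt_molecule("c", "circular",
                                      lay[((seq_len(nrow(lay)) - 1 + k) %%
                                             nrow(lay)) + 1, ])))
    expect_equal(config_key(invert_across(gg, cfg, "r")),
                 config_key(invert_across(gg, rot, "r")))
  }
})

test_that("excision and integration are mutually inverse and conserve content", {
  g <- single_pair_genome(direct = TRUE)
  c0 <- initial_config(g)
  c1 <- excise_across(g, c0, "rep")
  expect_equal(length(c1$molecules), 2)
  for (m in c1$molecules)
    expect_equal(sum(m$layout$segment_id == "R"), 1)
  expect_equal(segment_multiset(c1), segment_multiset(c0))
  c2 <- integrate_across(g, c1, "rep")
  expect_equal(config_key(c2), config_key(c0))

  # property: integrate . excise == identity on random instances
  set.seed(300)
  for (i in 1:25) {
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    ids <- c("P", "Q", "S", "T", "U", "V")
    segs <- data.frame(segment_id = c("R", ids),
                       sequence = replicate(7, strrep("ACGT", 5)))
    lay <- data.frame(
      segment_id = c("R", sample(ids, n1), "R", sample(ids, n2)),
      orientation = c("+", sample(c("+", "-"), n1, replace = TRUE), "+",
                      sample(c("+", "-"), n2, replace = TRUE)))
    gg <- mt_genome(segs, list(mt_molecule("c", "circular", lay)),
                    repeat_pairs = data.frame(pair_id = "r",
                                              segment_id = "R", length = 20L,
                                              identity = 1, enabled = TRUE))
    cfg <- initial_config(gg)
    back <- integrate_across(gg, excise_across(gg, cfg, "r"), "r")
    expect_equal(config_key(back), config_key(cfg))
    expect_equal(segment_multiset(back), segment_multiset(cfg))
  }
})

test_that("moves refuse inapplicable geometry", {
  g_dir <- single_pair_genome(direct = TRUE)
  g_inv <- single_pair_genome(direct = FALSE)
  expect_error(invert_across(g_dir, initial_config(g_dir), "rep"),
               "direct orientation")
  expect_error(excise_across(g_inv, initial_config(g_inv), "rep"),
               "inverted orientation")
  expect_error(integrate_across(g_dir, initial_config(g_dir), "rep"),
               "co-located")
  split <- excise_across(g_dir, initial_config(g_dir), "rep")
  expect_error(excise_across(g_dir, split, "rep"), "not co-located")
  # one copy missing
  one <- mt_config(list(split$molecules[[1]]))
  expect_error(integrate_across(g_dir, one, "rep"), "two copies")
})

test_that("state enumeration matches hand counts and is order-independent", {
  # no repeat pairs -> the initial state only
  g0 <- mt_genome(data.frame(segment_id = "P", sequence = strrep("ACGT", 10)),
                  list(mt_molecule("c", "circular",
                                   data.frame(segment_id = "P",
                                              orientation = "+"))))
  expect_equal(length(enumerate_states(g0)$states), 1)

  # a single direct pair on a circle: joint and excised, 2 states
  g1 <- single_pair_genome(direct = TRUE)
  expect_equal(length(enumerate_states(g1)$states), 2)

  # a single inverted pair: the inversion flips the inter-copy arc, giving
  # exactly the original and the inverted state
  g2 <- single_pair_genome(direct = FALSE)
  expect_equal(length(enumerate_states(g2)$states), 2)

  # two alternating inverted pairs: 3 joint + 1 separated
  sp <- enumerate_states(toy$genome)
  nmol <- vapply(sp$states, function(s) length(s$molecules), 0L)
  expect_equal(sum(nmol == 1), 3)
  expect_equal(sum(nmol == 2), 1)

  # order independence: start enumeration from every reachable state
  keys <- names(sp$states)
  for (s in sp$states) {
    sp_alt <- enumerate_states(toy$genome, initial = s)
    expect_equal(names(sp_alt$states), keys)
  }

  # content conservation across the whole state space
  base <- segment_multiset(initial_config(toy$genome))
  for (s in sp$states) expect_equal(segment_multiset(s), base)

  # the guard trips rather than truncating silently
  expect_error(enumerate_states(toy$genome, max_states = 2), "max_states")
})

test_that("low-identity or disabled pairs do not recombine", {
  g <- single_pair_genome(direct = TRUE)
  g$repeat_pairs$identity <- 0.94
  expect_equal(length(enumerate_states(g)$states), 2)
  g$repeat_pairs$identity <- 0.90  # below the mobility threshold
  expect_equal(length(enumerate_states(g)$states), 1)
  g$repeat_pairs$identity <- 1
  g$repeat_pairs$enabled <- FALSE
  expect_equal(length(enumerate_states(g)$states), 1)
})

test_that("transcriptional context of cob matches the two-pair geometry", {
  g <- toy$genome
  sp <- enumerate_states(g)
  ctx <- context_by_state(g, sp, "cob")
  joint <- ctx[ctx$n_molecules == 1, ]
  sep <- ctx[ctx$n_molecules == 2, ]
  expect_equal(nrow(joint), 3)
  expect_equal(nrow(sep), 1)
  # full cob transcribed from its own promoter in exactly 2 of 3 joint states
  expect_equal(sum(joint$full_promoter_gene == "cob"), 2)
  expect_equal(sum(joint$full_promoter_gene == "bobt"), 1)
  # the 5'-partial cob copy sits downstream of bobt in exactly 2 of 3
  expect_equal(sum(joint$partial_promoter_gene == "bobt"), 2)
  # on the separated molecule, cob is co-transcribed with bobt
  expect_equal(sep$full_promoter_gene, "bobt")

  # the separated state: bobt and full cob share one molecule, bobt first
  sep_cfg <- sp$states[[which(vapply(sp$states, function(s)
    length(s$molecules), 0L) == 2)]]
  found <- FALSE
  for (m in sep_cfg$molecules) {
    tu <- transcription_units(g, m)
    bobt_unit <- tu[tu$promoter_gene == "bobt", ]
    if (nrow(bobt_unit)) {
      cob_rank <- bobt_unit$rank[bobt_unit$gene_name == "cob"]
      bobt_rank <- bobt_unit$rank[bobt_unit$gene_name == "bobt"]
      if (length(cob_rank) && length(bobt_rank)) {
        expect_gt(cob_rank[1], bobt_rank[1])
        found <- TRUE
      }
    }
  }
  expect_true(found)
})

test_that("a gene with no upstream promoter on a linear molecule reports no-promoter", {
  segs <- data.frame(segment_id = c("P", "Q"),
                     sequence = c(strrep("ACGT", 100), strrep("GGCA", 100)))
  feats <- data.frame(feature_id = c("gene1", "prom1"),
                      segment_id = c("P", "Q"),
                      start = c(10L, 50L), end = c(100L, 80L),
                      strand = c("+", "+"),
                      kind = c("gene", "promoter"),
                      gene_name = c("g1", "other"))
  g <- mt_genome(segs, list(mt_molecule("lin", "linear",
                                        parse_layout(c("P+", "Q+")))),
                 features = feats)
  ctx <- transcription_context(g, initial_config(g), "g1")
  expect_equal(ctx$promoter_gene, "no-promoter")
})
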