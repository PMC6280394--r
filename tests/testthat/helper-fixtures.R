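# Shared fixture builders; everything is generated in code.

toy <- build_toy_genome()  # deterministic default seed

# random circular layout over a small alphabet, as an mt_molecule
random_circle <- function(n_segments = 6) {
  ids <- sample(LETTERS[1:8], n_segments, replace = TRUE)
  ori <- sample(c("+", "-"), n_segments, replace = TRUE)
  mt_molecule("rnd", "circular",
              data.frame(segment_id = ids, orientation = ori))
}

# genome with one circular molecule holding a single repeat pair, for
# hand-enumerable state counts; `direct` controls the pair orientation
single_pair_genome <- function(direct = TRUE) {
  segs <- data.frame(segment_id = c("R", "P", "Q"),
                     sequence = c(strrep("ACGT", 30), strrep("GATTACA", 40),
                                  strrep("TTGCA", 50)))
  lay <- data.frame(segment_id = c("R", "P", "R", "Q"),
                    orientation = c("+", "+", if (direct) "+" else "-", "+"))
  mt_genome(segs, list(mt_molecule("chr", "circular", lay)),
            repeat_pairs = data.frame(pair_id = "rep", segment_id = "R",
                                      length = 120L, identity = 1,
                                      enabled = TRUE))
}

# multiset of segment ids across a configuration (orientation ignored)
segment_multiset <- function(config) {
  sort(unlist(lapply(config$molecules, function(m) m$layout$segment_id)))
}

# canonical layout key of a molecule
layout_key <- function(m) attr(canonicalize(m), "key")

# inputs for an end-to-end pipeline run, written under `dir`
make_run_inputs <- function(dir, seed = 1) {
  # editing pileup with known rates (0.97 edited, 0.5 mid, 0.05 below call)
  pil <- simulate_pileup(c(0.97, 0.5, 0.05), depth = 200, seed = seed)
  write_pileup(pil[, 1:8], file.path(dir, "pileup.tsv"))

  panel <- toy_expression_panel()
  sim <- simulate_coverage(panel, seed = seed)
  cts <- data.frame(feature = panel$feature, length = panel$length,
                    sim$counts, check.names = FALSE)
  utils::write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  w <- data.frame(molecule = "1", start = as.integer(seq(0, 4900, 100)),
                  count = 200)
  w$count[w$start %in% c(1500, 1600, 1700)] <- 30000
  utils::write.table(w, file.path(dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(
    seed = seed, output_dir = file.path(dir, "out"),
    genome = list(synthetic = "toy"),
    recombination = list(genes = list("cob", "bobt")),
    editing = list(pileup = file.path(dir, "pileup.tsv")),
    compare = list(map = system.file("extdata", "kra_kov_editing_sites.tsv",
                                     package = "mtrecomb")),
    coverage = list(windows = file.path(dir, "windows.tsv"),
                    counts = file.path(dir, "counts.tsv"),
                    sample_sheet = file.path(dir, "samples.tsv"),
                    fold_change_features = list("bobt")))
}
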