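## Seeded synthetic-data generators: the two-repeat-pair toy genome whose
## recombination behaviour mirrors the joint-chromosome geometry (two
## inverted repeat pairs in alternating order), binomial editing pileups
## with known true rates, negative-binomial gendered coverage, and
## haplotype mutation with a known true alignment. All generators are
## bit-reproducible given (parameters, seed).

#' Random nucleotide sequence
#'
#' Uniform base composition unless a GC target is given. Uses the current
#' RNG stream; callers set the seed.
#'
#' @param n length in bases.
#' @param gc target GC fraction (default 0.5).
#' @return A character scalar.
#' @export
random_sequence <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Specification of the two-repeat-pair toy genome
#'
#' One circular "joint" molecule carrying two repeat pairs in alternating,
#' mutually inverted configuration: an atp6-derived repeat (A) and a
#' cob-derived repeat (C, 454 bp of 5' coding sequence plus 37 bp of
#' upstream sequence). Spacer segments X, Y, Z, W carry the cob promoter
#' (end of X, abutting C+), the cob 3' continuation (start of Y), the atp6
#' 3' continuation (end of Y, minus strand, abutting A-), and the chimeric
#' gene bobt with its promoter (in W, minus strand, pointing into C-).
#' Defaults give a joint molecule of roughly 12 kb.
#'
#' @param atp6_repeat_len length of the atp6 repeat (default 636).
#' @param cob_coding_len,cob_upstream_len parts of the cob repeat
#'   (defaults 454 and 37).
#' @param spacers named lengths for segments X, Y, Z, W.
#' @param gc GC fraction of the random sequences.
#' @return A list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(atp6_repeat_len = 636, cob_coding_len = 454,
                            cob_upstream_len = 37,
                            spacers = c(X = 2600, Y = 2600, Z = 2300,
                                        W = 2250),
                            gc = 0.45) {
  stopifnot(cob_coding_len > 0, cob_upstream_len > 0,
            all(c("X", "Y", "Z", "W") %in% names(spacers)),
            all(spacers >= 1000))
  structure(list(atp6_repeat_len = atp6_repeat_len,
                 cob_repeat_len = cob_coding_len + cob_upstream_len,
                 cob_coding_len = cob_coding_len,
                 cob_upstream_len = cob_upstream_len,
                 spacers = spacers, gc = gc),
            class = "toy_genome_spec")
}

#' Build the two-repeat-pair toy genome
#'
#' Constructs the segmented genome and its initial (joint, single-circle)
#' configuration: layout `[A+, X+, C+, Y+, A-, Z+, C-, W+]` with both
#' repeat pairs inverted. Enumerating its states yields exactly 3
#' joint-chromosome configurations and 1 separated two-molecule state; the
#' full cob gene is driven by its own promoter in 2 of the 3 joint states
#' and by the bobt promoter otherwise, and on the separated molecule cob is
#' co-transcribed with bobt.
#'
#' @param spec a [toy_genome_spec()].
#' @param seed RNG seed for the random sequences.
#' @return A list: `genome` (an `mt_genome`), `config` (the initial
#'   `mt_config`).
#' @export
build_toy_genome <- function(spec = toy_genome_spec(), seed = 1905) {
  set.seed(seed)
  sp <- spec$spacers
  segs <- data.frame(
    segment_id = c("A", "C", "X", "Y", "Z", "W"),
    sequence = c(random_sequence(spec$atp6_repeat_len, spec$gc),
                 random_sequence(spec$cob_repeat_len, spec$gc),
                 random_sequence(sp[["X"]], spec$gc),
                 random_sequence(sp[["Y"]], spec$gc),
                 random_sequence(sp[["Z"]], spec$gc),
                 random_sequence(sp[["W"]], spec$gc)))
  crl <- spec$cob_repeat_len
  feats <- data.frame(
    feature_id = c("atp6_repeat", "atp6_5p",
                   "cob_repeat", "cob_5p",
                   "cob_promoter", "cob_3p", "atp6_3p",
                   "bobt", "bobt_promoter"),
    segment_id = c("A", "A", "C", "C", "X", "Y", "Y", "W", "W"),
    start = c(0L, 0L, 0L, spec$cob_upstream_len,
              sp[["X"]] - 36L, 0L, sp[["Y"]] - 400L, 40L, 748L),
    end = c(spec$atp6_repeat_len, spec$atp6_repeat_len, crl, crl,
            sp[["X"]], 600L, sp[["Y"]], 748L, 784L),
    strand = c("+", "+", "+", "+", "+", "+", "-", "-", "-"),
    kind = c("repeat_copy", "gene", "repeat_copy", "gene",
             "promoter", "gene", "gene", "gene", "promoter"),
    gene_name = c(NA, "atp6", NA, "cob", "cob", "cob", "atp6",
                  "bobt", "bobt"))
  overlap_check(feats)
  pairs <- data.frame(pair_id = c("atp6", "cob"),
                      segment_id = c("A", "C"),
                      length = c(spec$atp6_repeat_len, crl),
                      identity = c(1, 1), enabled = TRUE)
  joint <- mt_molecule("joint", "circular",
                       parse_layout(c("A+", "X+", "C+", "Y+",
                                      "A-", "Z+", "C-", "W+")))
  genome <- mt_genome(segs, list(joint), feats, pairs)
  list(genome = genome, config = initial_config(genome))
}

## gene/promoter features must not collide on a segment (repeat_copy
## markers span whole segments by design and are exempt)
overlap_check <- function(feats) {
  f <- feats[feats$kind != "repeat_copy", , drop = FALSE]
  for (seg in unique(f$segment_id)) {
    fs <- f[f$segment_id == seg & f$strand != "", , drop = FALSE]
    for (strand in unique(fs$strand)) {
      g <- fs[fs$strand == strand, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping feature placement on segment ", seg)
    }
  }
  invisible(TRUE)
}

#' Simulate an editing pileup with known true rates
#'
#' Per site, the T (edited) count is Binomial(depth, true rate) and the C
#' count is the remainder; other bases get no reads. Deterministic under
#' the seed.
#'
#' @param rates numeric vector of true editing rates in `[0, 1]`.
#' @param depth per-site read depth (scalar or vector).
#' @param seed RNG seed.
#' @param molecule molecule id for the output rows.
#' @param positions 0-based positions (default consecutive from 0).
#' @return An oriented pileup data.frame with a `true_rate` column.
#' @export
simulate_pileup <- function(rates, depth, seed = 1, molecule = "1",
                            positions = seq_along(rates) - 1L) {
  stopifnot(all(rates >= 0 & rates <= 1), all(depth >= 1))
  set.seed(seed)
  n <- length(rates)
  depth <- rep_len(depth, n)
  t_counts <- stats::rbinom(n, depth, rates)
  data.frame(molecule = molecule, pos = positions, ref = "C", strand = "+",
             nA = 0L, nC = depth - t_counts, nG = 0L, nT = t_counts,
             true_rate = rates)
}

#' Simulate gendered coverage count tables
#'
#' Counts are negative-binomial with mean `base_tpm x gender effect x
#' length/1000 x depth_factor` and variance `mu + dispersion * mu^2`
#' (Poisson when `dispersion == 0`). The gender effect multiplies female
#' (F) sample means; hermaphrodite (H) means use effect 1.
#'
#' @param features data.frame with `feature`, `length`, `base_tpm`, and
#'   `f_effect` (fold effect in F relative to H, e.g. 3 for a 3-fold
#'   female-biased feature).
#' @param n_per_gender samples per gender (default 3).
#' @param dispersion negative-binomial dispersion alpha (default 0.05).
#' @param depth_factor scales expected counts (default 1).
#' @param seed RNG seed.
#' @return A list: `counts` (features x samples matrix), `samples`
#'   (data.frame `sample`, `gender`), `expected` (matrix of means).
#' @export
simulate_coverage <- function(features, n_per_gender = 3, dispersion = 0.05,
                              depth_factor = 1, seed = 1) {
  stopifnot(all(features$f_effect > 0), all(features$base_tpm >= 0))
  set.seed(seed)
  samples <- data.frame(
    sample = c(paste0("F", seq_len(n_per_gender)),
               paste0("H", seq_len(n_per_gender))),
    gender = rep(c("F", "H"), each = n_per_gender))
  mu <- outer(seq_len(nrow(features)), seq_len(nrow(samples)),
              function(i, j)
                features$base_tpm[i] * (features$length[i] / 1000) *
                depth_factor *
                ifelse(samples$gender[j] == "F", features$f_effect[i], 1))
  counts <- matrix(0L, nrow(features), nrow(samples),
                   dimnames = list(features$feature, samples$sample))
  for (j in seq_len(ncol(counts))) {
    counts[, j] <- if (dispersion == 0) stats::rpois(nrow(mu), mu[, j])
    else stats::rnbinom(nrow(mu), mu = mu[, j], size = 1 / dispersion)
  }
  dimnames(mu) <- dimnames(counts)
  list(counts = counts, samples = samples, expected = mu)
}

#' Deterministic toy expression panel with a planted gender effect
#'
#' A small mitochondrial-transcriptome-like feature panel: one chimeric
#' candidate gene (`bobt`, 708 bp ORF scale) expressed 3-fold higher in
#' females, against a background of genes spanning roughly two orders of
#' magnitude in expression, so that the planted feature contributes only a
#' small share of the library and TPM ratios are not distorted by
#' compositional effects.
#'
#' @param n_background number of background genes (default 29).
#' @param bobt_effect planted F/H fold effect on bobt (default 3).
#' @param seed RNG seed for the background draws.
#' @return A features data.frame for [simulate_coverage()].
#' @export
toy_expression_panel <- function(n_background = 29, bobt_effect = 3,
                                 seed = 2018) {
  set.seed(seed)
  data.frame(
    feature = c("bobt", paste0("g", seq_len(n_background))),
    length = c(708, sample(300:3000, n_background, replace = TRUE)),
    base_tpm = c(60, exp(stats::runif(n_background, log(50), log(8000)))),
    f_effect = c(bobt_effect, rep(1, n_background)))
}

#' Mutate a haplotype and emit the true alignment
#'
#' Applies the requested number of substitutions and single-base indels at
#' positions sampled without replacement; substitutions never recreate the
#' original base. Indels alternate deletion/insertion. The gap-annotated
#' true alignment of (original, mutant) is returned alongside the mutant
#' sequence.
#'
#' @param seq nucleotide string.
#' @param n_substitutions,n_indels mutation counts.
#' @param seed RNG seed.
#' @return A list: `sequence` (mutant, ungapped), `aligned_a` (original
#'   with gaps), `aligned_b` (mutant with gaps), `positions` (0-based, per
#'   mutation type).
#' @export
mutate_haplotype <- function(seq, n_substitutions = 0, n_indels = 0,
                             seed = 1) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  stopifnot(n_substitutions + n_indels <= n)
  set.seed(seed)
  pos <- if (n_substitutions + n_indels > 0)
    sample.int(n, n_substitutions + n_indels) else integer()
  sub_pos <- sort(pos[seq_len(n_substitutions)])
  ind_pos <- sort(pos[seq_len(n_indels) + n_substitutions])
  op <- rep("M", n)
  op[sub_pos] <- "S"
  if (length(ind_pos))
    op[ind_pos] <- rep(c("D", "I"), length.out = length(ind_pos))
  a <- character(0); b <- character(0)
  for (i in seq_len(n)) {
    base <- s[i]
    if (op[i] == "M") {
      a <- c(a, base); b <- c(b, base)
    } else if (op[i] == "S") {
      a <- c(a, base)
      b <- c(b, sample(setdiff(c("A", "C", "G", "T"), base), 1))
    } else if (op[i] == "D") {
      a <- c(a, base); b <- c(b, "-")
    } else {  # insertion before the kept base
      a <- c(a, "-", base)
      b <- c(b, sample(c("A", "C", "G", "T"), 1), base)
    }
  }
  list(sequence = paste(b[b != "-"], collapse = ""),
       aligned_a = paste(a, collapse = ""),
       aligned_b = paste(b, collapse = ""),
       positions = list(substitutions = sub_pos - 1L,
                        indels = ind_pos - 1L))
}
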