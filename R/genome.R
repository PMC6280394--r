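## Core genome representation: chromosomes as ordered signed segments with
## features and repeat pairs, plus the sequence metrics shared by all stages.
## Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
## inclusive; report files use 1-based positions.

#' Construct a segmented genome
#'
#' A segmented genome holds the building blocks shared by all analysis
#' stages: unique sequence segments, molecules described as ordered oriented
#' segments, features anchored to segments (0-based half-open local
#' coordinates), and annotated repeat pairs. Repeat copies of a pair share a
#' single segment id, so a pair is present wherever that segment occurs
#' twice across a configuration.
#'
#' @param segments data.frame with columns `segment_id`, `sequence`
#'   (A/C/G/T/N strings).
#' @param molecules list of [mt_molecule()] objects.
#' @param features data.frame with columns `feature_id`, `segment_id`,
#'   `start`, `end` (0-based half-open within the segment), `strand`
#'   (`"+"`/`"-"`), `kind`, `gene_name` (NA allowed).
#' @param repeat_pairs data.frame with columns `pair_id`, `segment_id`,
#'   `length`, `identity` (fraction), `enabled` (logical).
#' @return An object of class `mt_genome`.
#' @export
mt_genome <- function(segments, molecules, features = NULL,
                      repeat_pairs = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("segment_id", "sequence") %in% names(segments)))
  if (anyDuplicated(segments$segment_id))
    stop("segment ids must be unique within a genome")
  segments$sequence <- toupper(segments$sequence)
  bad <- grepl("[^ACGTN]", segments$sequence)
  if (any(bad))
    stop("segment sequence contains non-ACGTN characters: ",
         segments$segment_id[bad][1])
  segments$length <- nchar(segments$sequence)
  if (any(segments$length < 1)) stop("segments must have length >= 1")

  if (is.null(features))
    features <- data.frame(feature_id = character(), segment_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), kind = character(),
                           gene_name = character())
  if (!"gene_name" %in% names(features)) features$gene_name <- NA_character_
  seg_len <- stats::setNames(segments$length, segments$segment_id)
  if (nrow(features)) {
    if (!all(features$segment_id %in% segments$segment_id))
      stop("feature on unknown segment")
    over <- features$end > seg_len[features$segment_id] | features$start < 0 |
      features$start >= features$end
    if (any(over))
      stop("feature extends beyond its segment: ", features$feature_id[over][1])
  }

  if (is.null(repeat_pairs))
    repeat_pairs <- data.frame(pair_id = character(), segment_id = character(),
                               length = integer(), identity = numeric(),
                               enabled = logical())
  if (!"enabled" %in% names(repeat_pairs)) repeat_pairs$enabled <- TRUE

  names(molecules) <- vapply(molecules, `[[`, "", "id")
  for (m in molecules)
    if (!all(m$layout$segment_id %in% segments$segment_id))
      stop("molecule ", m$id, " references unknown segment")

  structure(list(segments = segments, molecules = molecules,
                 features = features, repeat_pairs = repeat_pairs),
            class = "mt_genome")
}

#' Construct a molecule as an ordered list of oriented segments
#'
#' @param id molecule label.
#' @param topology `"circular"` or `"linear"`.
#' @param layout data.frame with columns `segment_id` and `orientation`
#'   (`"+"`/`"-"`), in molecule order.
#' @return An object of class `mt_molecule`.
#' @export
mt_molecule <- function(id, topology = c("circular", "linear"), layout) {
  topology <- match.arg(topology)
  if (is.character(layout))
    layout <- parse_layout(layout)
  stopifnot(is.data.frame(layout), nrow(layout) >= 1,
            all(layout$orientation %in% c("+", "-")))
  rownames(layout) <- NULL
  structure(list(id = id, topology = topology,
                 layout = layout[c("segment_id", "orientation")]),
            class = "mt_molecule")
}

## "A+" style tokens <-> layout data.frame
parse_layout <- function(tokens) {
  data.frame(segment_id = sub("[+-]$", "", tokens),
             orientation = sub("^.*([+-])$", "\\1", tokens))
}

layout_tokens <- function(layout) {
  paste0(layout$segment_id, layout$orientation)
}

#' @export
print.mt_molecule <- function(x, ...) {
  cat(sprintf("<mt_molecule %s> %s: %s\n", x$id, x$topology,
              paste(layout_tokens(x$layout), collapse = " ")))
  invisible(x)
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %d segment(s), %d molecule(s), %d feature(s), %d repeat pair(s)\n",
              nrow(x$segments), length(x$molecules), nrow(x$features),
              nrow(x$repeat_pairs)))
  for (m in x$molecules) print(m)
  invisible(x)
}

segment_lengths <- function(genome) {
  stats::setNames(genome$segments$length, genome$segments$segment_id)
}

segment_sequences <- function(genome) {
  stats::setNames(genome$segments$sequence, genome$segments$segment_id)
}

#' Total length of a molecule in bases
#' @param genome an `mt_genome`.
#' @param molecule an `mt_molecule` (or molecule id in `genome`).
#' @return Integer length.
#' @export
molecule_length <- function(genome, molecule) {
  molecule <- resolve_molecule(genome, molecule)
  sum(segment_lengths(genome)[molecule$layout$segment_id])
}

resolve_molecule <- function(genome, molecule) {
  if (is.character(molecule)) {
    if (!molecule %in% names(genome$molecules))
      stop("unknown molecule: ", molecule)
    molecule <- genome$molecules[[molecule]]
  }
  molecule
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Forward-strand sequence of a molecule
#'
#' Concatenates the segment sequences along the molecule layout, reverse
#' complementing segments placed in `-` orientation.
#' @inheritParams molecule_length
#' @return A character scalar.
#' @export
molecule_sequence <- function(genome, molecule) {
  molecule <- resolve_molecule(genome, molecule)
  seqs <- segment_sequences(genome)[molecule$layout$segment_id]
  neg <- molecule$layout$orientation == "-"
  if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
  paste(seqs, collapse = "")
}

#' Percent nucleotide identity excluding indels
#'
#' Computes 100 x matches / columns-where-neither-sequence-has-a-gap over a
#' pairwise alignment. Columns containing a gap in either sequence are
#' excluded from both numerator and denominator; `N` never matches anything
#' but still occupies a column. The result is rounded half-up to 2 decimals.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length
#'   (alphabet A/C/G/T/N/-).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("ACGT", "ACGA")  # 75
percent_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal lengths")
  ok <- a %in% c("A", "C", "G", "T", "N", "-") &
    b %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) stop("alphabet must be A/C/G/T/N/-")
  keep <- a != "-" & b != "-"
  n <- sum(keep)
  if (n == 0L) stop("no gap-free columns: identity undefined")
  matches <- sum(a[keep] == b[keep] & a[keep] != "N")
  round_half_up(100 * matches / n, 2)
}

## round() uses banker's rounding; reported identities use half-up
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' G+C content of a sequence
#'
#' 100 x (G+C) / (A+C+G+T); `N` bases are excluded from the denominator.
#' @param seq nucleotide string.
#' @return Percentage.
#' @export
gc_content <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (!length(s)) stop("empty sequence")
  denom <- sum(s %in% c("A", "C", "G", "T"))
  if (denom == 0L) stop("sequence has no unambiguous bases")
  100 * sum(s %in% c("G", "C")) / denom
}

#' Fraction of a genome occupied by a region, as a percentage
#'
#' @param part_bp bases in the region of interest.
#' @param total_bp total genome size in bases.
#' @return Percentage rounded to 1 decimal place.
#' @export
fraction_of_genome <- function(part_bp, total_bp) {
  if (total_bp <= 0) stop("total must be positive")
  if (part_bp < 0 || part_bp > total_bp)
    stop("part must lie in [0, total]")
  round_half_up(100 * part_bp / total_bp, 1)
}

#' In-silico restriction digest of a molecule
#'
#' Splits a molecule at the given cut positions and returns the fragment
#' lengths, sorted descending. A circular molecule with k sites yields k
#' fragments (linearised at the first site); a linear molecule yields k + 1.
#' Fragment lengths always sum to the molecule length.
#'
#' @param molecule an `mt_molecule`, or an integer molecule length.
#' @param sites integer cut positions (0-based) on the molecule.
#' @param genome the `mt_genome` (needed when `molecule` is an
#'   `mt_molecule` or id).
#' @param topology used when `molecule` is given as a bare length.
#' @return Integer vector of fragment lengths. A circular molecule with no
#'   sites returns its full length with attribute `uncut = TRUE`.
#' @export
digest <- function(molecule, sites, genome = NULL,
                   topology = c("circular", "linear")) {
  if (inherits(molecule, "mt_molecule") || is.character(molecule)) {
    molecule <- resolve_molecule(genome, molecule)
    len <- molecule_length(genome, molecule)
    topology <- molecule$topology
  } else {
    len <- as.integer(molecule)
    topology <- match.arg(topology)
  }
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) && (min(sites) < 0 || max(sites) > len))
    stop("cut site outside molecule")
  if (topology == "circular") {
    if (!length(sites)) {
      out <- len
      attr(out, "uncut") <- TRUE
      return(out)
    }
    frags <- diff(c(sites, sites[1] + len))
  } else {
    frags <- diff(c(0L, sites, len))
    frags <- frags[frags > 0 | length(frags) == 1]
  }
  sort(as.integer(frags), decreasing = TRUE)
}

#' Instantiate segment-anchored features onto molecule coordinates
#'
#' Walks the molecule layout and places every feature of every segment
#' occurrence into forward-strand molecule coordinates (0-based half-open),
#' flipping coordinates and strand for `-` oriented occurrences. Because a
#' repeat segment can occur more than once, a feature may yield several
#' instances; instances are suffixed with the occurrence index.
#'
#' @inheritParams molecule_length
#' @return data.frame with columns `instance_id`, `feature_id`, `start`,
#'   `end`, `strand`, `kind`, `gene_name`, `occurrence`.
#' @export
instantiate_features <- function(genome, molecule) {
  molecule <- resolve_molecule(genome, molecule)
  lay <- molecule$layout
  lens <- segment_lengths(genome)[lay$segment_id]
  offs <- c(0L, cumsum(lens))[seq_len(nrow(lay))]
  out <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    fs <- genome$features[genome$features$segment_id == lay$segment_id[i], ,
                          drop = FALSE]
    if (!nrow(fs)) next
    L <- lens[[i]]
    if (lay$orientation[i] == "+") {
      start <- offs[i] + fs$start
      end <- offs[i] + fs$end
      strand <- fs$strand
    } else {
      start <- offs[i] + (L - fs$end)
      end <- offs[i] + (L - fs$start)
      strand <- ifelse(fs$strand == "+", "-", "+")
    }
    out[[i]] <- data.frame(instance_id = paste0(fs$feature_id, "@", i),
                           feature_id = fs$feature_id,
                           start = as.integer(start), end = as.integer(end),
                           strand = strand, kind = fs$kind,
                           gene_name = fs$gene_name, occurrence = i)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(instance_id = character(), feature_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      kind = character(), gene_name = character(),
                      occurrence = integer())
  out[order(out$start, out$instance_id), , drop = FALSE]
}
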