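## Transcript coverage: TPM normalisation, windowed detection of intergenic
## transcription islands, repeat-aware unique-region depth, and gender
## (female vs hermaphrodite) fold changes.

#' Island detection parameters
#'
#' Windows are non-overlapping tiles by default (`step == window`), which
#' matches counting reads per window against a single threshold; an
#' overlapping mode is available by setting `step < window`. The count
#' threshold applies to reads merged across all samples; because such a
#' threshold is tied to sequencing depth, `rescale_depth` allows
#' `threshold * total_depth / reference_depth` scaling for datasets of a
#' different size.
#'
#' @param window window size in bases (default 100).
#' @param step step in bases (default 100).
#' @param merged_count_threshold reads per window in the merged data
#'   (default 12000).
#' @param min_island_windows minimum qualifying windows per island
#'   (default 1).
#' @param rescale_depth optional `c(total, reference)` depths used to
#'   rescale the threshold.
#' @return A list of class `island_params`.
#' @export
island_params <- function(window = 100, step = 100,
                          merged_count_threshold = 12000,
                          min_island_windows = 1, rescale_depth = NULL) {
  stopifnot(window >= step, step > 0, merged_count_threshold > 0)
  thr <- merged_count_threshold
  if (!is.null(rescale_depth))
    thr <- thr * rescale_depth[1] / rescale_depth[2]
  structure(list(window = window, step = step,
                 merged_count_threshold = thr,
                 min_island_windows = min_island_windows),
            class = "island_params")
}

#' TPM-normalise a count table
#'
#' `tpm[i, s] = (count[i, s] / length_kb[i]) / sum_j(count[j, s] /
#' length_kb[j]) * 1e6`; every sample column sums to one million over the
#' feature universe used for normalisation.
#'
#' @param counts numeric matrix or data.frame, features x samples.
#' @param lengths feature lengths in bases (recycled along rows).
#' @return A matrix of TPM values with the input dimnames.
#' @export
tpm_normalize <- function(counts, lengths) {
  m <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- m / (lengths / 1000)
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero] %||% which(zero), collapse = ", "))
  sweep(rate, 2, totals, "/") * 1e6
}

#' Tile a molecule into count windows
#'
#' Helper producing the window frame used by [detect_islands()] from a
#' per-base count vector.
#'
#' @param depth numeric per-base counts (merged across samples).
#' @param molecule molecule id for the output.
#' @param params an [island_params()] object.
#' @return data.frame `molecule`, `start` (0-based), `count` (sum of
#'   per-base counts in the window).
#' @export
tile_windows <- function(depth, molecule = "1", params = island_params()) {
  n <- length(depth)
  starts <- seq(0L, max(0L, n - 1L), by = params$step)
  starts <- starts[starts + params$window <= n | starts == 0L]
  data.frame(molecule = molecule, start = as.integer(starts),
             count = vapply(starts, function(s)
               sum(depth[(s + 1):min(n, s + params$window)]), 0))
}

#' Detect intergenic transcription islands
#'
#' Windows overlapping any annotated gene/ORF are masked out first (islands
#' are defined in intergenic regions), remaining windows with merged count
#' at or above the threshold are kept and merged when adjacent, and each
#' merged run becomes an island named `chromosome.start(length)` with a
#' 1-based start.
#'
#' @param windows data.frame with columns `molecule`, `start` (0-based
#'   window start), `count` (merged read count in the window).
#' @param gene_mask data.frame of masking features with columns `molecule`,
#'   `start`, `end` (0-based half-open); any overlap masks a window.
#' @param params an [island_params()] object.
#' @return data.frame of islands: `molecule`, `start` (0-based), `length`,
#'   `name`, `mean_count`, `n_windows`.
#' @export
detect_islands <- function(windows, gene_mask = NULL,
                           params = island_params()) {
  w <- windows[order(windows$molecule, windows$start), , drop = FALSE]
  w$end <- w$start + params$window
  masked <- rep(FALSE, nrow(w))
  if (!is.null(gene_mask) && nrow(gene_mask)) {
    for (i in seq_len(nrow(gene_mask)))
      masked <- masked | (w$molecule == gene_mask$molecule[i] &
                            w$start < gene_mask$end[i] &
                            w$end > gene_mask$start[i])
  }
  keep <- !masked & w$count >= params$merged_count_threshold
  out <- list()
  for (mol in unique(w$molecule)) {
    wi <- w[w$molecule == mol, , drop = FALSE]
    ki <- keep[w$molecule == mol]
    if (!any(ki)) next
    idx <- which(ki)
    ## adjacent = consecutive window starts (one step apart)
    brk <- c(0, which(diff(wi$start[idx]) != params$step), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      run <- idx[(brk[b] + 1):brk[b + 1]]
      if (length(run) < params$min_island_windows) next
      start <- wi$start[run[1]]
      len <- wi$end[run[length(run)]] - start
      out[[length(out) + 1L]] <- data.frame(
        molecule = mol, start = start, length = len,
        name = island_name(mol, start, len),
        mean_count = mean(wi$count[run]), n_windows = length(run))
    }
  }
  if (!length(out))
    return(data.frame(molecule = character(), start = integer(),
                      length = integer(), name = character(),
                      mean_count = numeric(), n_windows = integer()))
  do.call(rbind, out)
}

#' Island naming convention
#'
#' Islands are named `chromosome.start(length)` with a 1-based start, e.g.
#' `"1.371387(450)"`; ORFs use the same pattern with `(orf)` inserted.
#' `parse_island_name()` inverts the convention exactly.
#'
#' @param molecule chromosome label.
#' @param start 0-based start (converted to 1-based in the name).
#' @param length island length in bases.
#' @return `island_name()`: the name string. `parse_island_name()`: a list
#'   with `molecule`, `start` (0-based again), `length`.
#' @export
island_name <- function(molecule, start, length) {
  sprintf("%s.%d(%d)", molecule, start + 1L, length)
}

#' @rdname island_name
#' @param name an island name string.
#' @export
parse_island_name <- function(name) {
  m <- regmatches(name, regexec("^(.+)\\.([0-9]+)\\(([0-9]+)\\)$", name))[[1]]
  if (length(m) != 4) stop("not an island name: ", name)
  list(molecule = m[2], start = as.integer(m[3]) - 1L,
       length = as.integer(m[4]))
}

#' Mean depth over the positions unique to a feature
#'
#' Positions overlapping any repeat copy shared with another locus are
#' excluded before averaging, so coverage of e.g. a chimeric ORF is not
#' inflated by reads from the homologous parts of the donor genes.
#'
#' @param feature list or one-row data.frame with `start`, `end` (0-based
#'   half-open).
#' @param repeats data.frame of shared intervals with `start`, `end`.
#' @param depth per-base depth vector covering the molecule (element 1 is
#'   position 0).
#' @return A list: `mean_depth` (NA when fully masked, with `flag`
#'   `"fully_masked"`), `kept` (data.frame of retained intervals),
#'   `n_unique` bases.
#' @export
unique_region_coverage <- function(feature, repeats, depth) {
  pos <- seq.int(feature$start, feature$end - 1L)
  keep <- rep(TRUE, length(pos))
  if (!is.null(repeats) && nrow(repeats)) {
    for (i in seq_len(nrow(repeats)))
      keep <- keep & !(pos >= repeats$start[i] & pos < repeats$end[i])
  }
  if (!any(keep))
    return(list(mean_depth = NA_real_, flag = "fully_masked",
                kept = data.frame(start = integer(), end = integer()),
                n_unique = 0L))
  kp <- pos[keep]
  brk <- c(0, which(diff(kp) != 1), length(kp))
  kept <- data.frame(
    start = kp[brk[-length(brk)] + 1],
    end = kp[brk[-1]] + 1L)
  list(mean_depth = mean(depth[kp + 1L]), flag = NA_character_,
       kept = kept, n_unique = length(kp))
}

#' Gender fold change of a feature's expression
#'
#' Ratio of the arithmetic mean TPM in female (F) samples over the mean in
#' hermaphrodite (H) samples. When the H mean is zero, a pseudo-count of
#' 0.5 TPM is added to both means (noted in the result).
#'
#' @param coverage data.frame in long form: `feature`, `sample`, `tpm`.
#' @param samples data.frame with `sample`, `gender` (`"F"`/`"H"`).
#' @param feature feature id to evaluate.
#' @return A list: `ratio` (F/H), `mean_f`, `mean_h`, `direction`
#'   (`"F>H"`, `"H>F"` or `"equal"`), `pseudo_count` flag.
#' @export
gender_fold_change <- function(coverage, samples, feature) {
  cv <- coverage[coverage$feature == feature, , drop = FALSE]
  cv$gender <- samples$gender[match(cv$sample, samples$sample)]
  if (!all(c("F", "H") %in% cv$gender))
    stop("both genders are required; missing: ",
         paste(setdiff(c("F", "H"), cv$gender), collapse = ", "))
  mf <- mean(cv$tpm[cv$gender == "F"])
  mh <- mean(cv$tpm[cv$gender == "H"])
  pseudo <- mh == 0
  if (pseudo) { mf <- mf + 0.5; mh <- mh + 0.5 }
  ratio <- mf / mh
  list(ratio = ratio, mean_f = mf, mean_h = mh,
       direction = if (ratio > 1) "F>H" else if (ratio < 1) "H>F" else
         "equal",
       pseudo_count = pseudo)
}

#' Write islands as BED (0-based) and named TSV (1-based names)
#'
#' @param islands data.frame from [detect_islands()].
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @return Invisibly, the island table.
#' @export
write_islands <- function(islands, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", islands$molecule,
                     islands$start, islands$start + islands$length,
                     islands$name, round(islands$mean_count))
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(islands, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(islands)
}
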