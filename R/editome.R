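## Two-haplotype editome comparison at homologous positions: classify each
## mapped site pair as conserved, lost (by genomic C->T substitution or by
## cessation of editing activity), newly edited, highly differential, or a
## minor difference.

#' Thresholds for editome comparison
#'
#' A site pair is highly differential when the rate in one haplotype
#' exceeds `high` and the rate in the other is below `low` (strict
#' inequalities). A loss of editing activity at a retained genomic C
#' requires the silent side to show at most `loss_activity_max` edited
#' reads (0.1\% by default).
#'
#' @param high upper rate bound (default 0.8).
#' @param low lower rate bound (default 0.3).
#' @param loss_activity_max maximal residual rate on the lost side
#'   (default 0.001).
#' @param call an [editing_params()] object defining "called edited".
#' @return A list of class `comparison_thresholds`.
#' @export
comparison_thresholds <- function(high = 0.8, low = 0.3,
                                  loss_activity_max = 0.001,
                                  call = editing_params()) {
  stopifnot(low < high, loss_activity_max < low)
  structure(list(high = high, low = low,
                 loss_activity_max = loss_activity_max, call = call),
            class = "comparison_thresholds")
}

COMPARISON_CLASSES <- c("conserved_edited", "conserved_unedited",
                        "loss_substitution", "loss_activity", "new_editing",
                        "highly_differential", "minor_difference",
                        "unalignable")

#' Classify a homologous site pair across two haplotypes
#'
#' Decision order (first match wins):
#' \enumerate{
#'   \item `loss_substitution`: exactly one reference base is T where the
#'     other is a C edited above the call threshold (the DNA-level change
#'     dominates the RNA-level comparison).
#'   \item `loss_activity`: both references C, one rate at least `high`,
#'     the other recorded at or below `loss_activity_max`.
#'   \item `highly_differential`: both references C, both rates recorded,
#'     the larger above `high` and the smaller below `low` (strict).
#'   \item `new_editing`: both references C, one side called edited, the
#'     other with no recorded editing (missing rate) or a rate below the
#'     call threshold without being a recorded editing site.
#'   \item otherwise `conserved_edited` (both called),
#'     `conserved_unedited` (neither called), or `minor_difference`.
#' }
#' A missing (`NA`) rate means the haplotype's editome has no record at the
#' site; a recorded near-zero rate is evidence of measured silence.
#' References outside \{C, T\} at a mapped editing row are flagged
#' `unalignable` and excluded from summaries.
#'
#' @param ref_a,ref_b reference bases in haplotypes a and b.
#' @param rate_a,rate_b editing rates (`NA` when not recorded).
#' @param thresholds a [comparison_thresholds()] object.
#' @return A character class label; attribute `direction` records which
#'   haplotype lost/gained where that is meaningful.
#' @export
classify_site_pair <- function(ref_a, ref_b, rate_a = NA_real_,
                               rate_b = NA_real_,
                               thresholds = comparison_thresholds()) {
  th <- thresholds
  called <- function(r) !is.na(r) && r >= th$call$min_rate
  lab <- function(class, direction = NA_character_) {
    attr(class, "direction") <- direction
    class
  }
  if (!ref_a %in% c("C", "T") || !ref_b %in% c("C", "T"))
    return(lab("unalignable"))
  ## 1. substitution loss: DNA-level C -> T in one haplotype
  if (ref_a == "T" && ref_b == "C" && called(rate_b))
    return(lab("loss_substitution", "a"))
  if (ref_b == "T" && ref_a == "C" && called(rate_a))
    return(lab("loss_substitution", "b"))
  if (ref_a != "C" || ref_b != "C")
    return(lab("conserved_unedited"))
  ## both references C from here on
  hi_a <- !is.na(rate_a); hi_b <- !is.na(rate_b)
  ## 2. activity loss: measured silence against a strong edit
  if (hi_a && hi_b) {
    if (rate_a >= th$high && rate_b <= th$loss_activity_max)
      return(lab("loss_activity", "b"))
    if (rate_b >= th$high && rate_a <= th$loss_activity_max)
      return(lab("loss_activity", "a"))
    ## 3. highly differential
    if (max(rate_a, rate_b) > th$high && min(rate_a, rate_b) < th$low)
      return(lab("highly_differential",
                 if (rate_a > rate_b) "a_high" else "b_high"))
  }
  ## 4. new editing: edited in one haplotype, the other with no editing
  ##    record (or recorded at essentially zero)
  if (called(rate_a) && (!hi_b || rate_b <= th$loss_activity_max))
    return(lab("new_editing", "a"))
  if (called(rate_b) && (!hi_a || rate_a <= th$loss_activity_max))
    return(lab("new_editing", "b"))
  ## 5. remainder
  if (called(rate_a) && called(rate_b)) return(lab("conserved_edited"))
  if (!called(rate_a) && !called(rate_b)) return(lab("conserved_unedited"))
  lab("minor_difference")
}

#' Compare two editomes over a homologous-site map
#'
#' @param map data.frame with one row per homologous site:
#'   `gene`, `position_a`, `position_b`, `ref_a`, `ref_b`, `rate_a`,
#'   `rate_b`, optionally `gene_class` (`"intact"`/`"chimeric"`),
#'   `codon_before`, `codon_after` (reference-haplotype codon and the codon
#'   after the C->T edit).
#' @param thresholds a [comparison_thresholds()] object.
#' @return The map with `class`, `direction`, and (when codons are given)
#'   `synonymous` columns; class `mt_editome_comparison`.
#' @export
compare_editomes <- function(map, thresholds = comparison_thresholds()) {
  cls <- character(nrow(map)); dir <- character(nrow(map))
  for (i in seq_len(nrow(map))) {
    k <- classify_site_pair(map$ref_a[i], map$ref_b[i],
                            as.numeric(map$rate_a[i]),
                            as.numeric(map$rate_b[i]), thresholds)
    cls[i] <- k
    dir[i] <- attr(k, "direction") %||% NA_character_
  }
  out <- map
  out$class <- cls
  out$direction <- dir
  if (all(c("codon_before", "codon_after") %in% names(map))) {
    out$synonymous <- vapply(seq_len(nrow(map)), function(i) {
      cb <- map$codon_before[i]; ca <- map$codon_after[i]
      if (is.na(cb) || is.na(ca)) return(NA)
      unname(Biostrings::GENETIC_CODE[cb] == Biostrings::GENETIC_CODE[ca])
    }, TRUE)
  }
  class(out) <- c("mt_editome_comparison", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise an editome comparison
#'
#' Deterministic counts by class, by gene, and by synonymy. Loss counts can
#' be restricted to intact protein-coding genes (excluding chimeric-ORF
#' partial genes), which is the natural unit when asking how many editing
#' sites a haplotype has genuinely lost.
#'
#' @param records a comparison table from [compare_editomes()].
#' @param losses_intact_only restrict loss counts to `gene_class ==
#'   "intact"` rows (default TRUE; requires a `gene_class` column,
#'   otherwise all rows count).
#' @return A list with `by_class` (named counts over all classes),
#'   `by_gene` (class x gene table), `by_synonymy`, `losses` (the possibly
#'   restricted loss count), `n` (rows, excluding unalignable).
#' @export
summarize_comparison <- function(records, losses_intact_only = TRUE) {
  r <- records[records$class != "unalignable", , drop = FALSE]
  by_class <- vapply(setdiff(COMPARISON_CLASSES, "unalignable"),
                     function(k) sum(r$class == k), 0L)
  loss <- r[r$class %in% c("loss_substitution", "loss_activity"), ,
            drop = FALSE]
  if (losses_intact_only && "gene_class" %in% names(loss))
    loss <- loss[loss$gene_class == "intact", , drop = FALSE]
  by_gene <- if (nrow(r)) table(r$gene, r$class) else table(character())
  by_syn <- if ("synonymous" %in% names(r))
    table(class = r$class, synonymous = r$synonymous) else NULL
  list(by_class = by_class, by_gene = by_gene, by_synonymy = by_syn,
       losses = nrow(loss), n = nrow(r))
}

#' Correlation of editing rates between two haplotypes
#'
#' Rank correlation (primary) and linear correlation (secondary) over
#' mapped sites where both references are C and both rates are recorded,
#' optionally restricted to a subset by synonymy or context.
#'
#' @param records a comparison table from [compare_editomes()].
#' @param subset `"all"`, `"synonymous"`, `"non-synonymous"`, or a context
#'   label such as `"intronic"` matched against a `context` column.
#' @return A list with `spearman`, `pearson`, and `n`.
#' @export
rate_correlation <- function(records, subset = "all") {
  r <- records[records$ref_a == "C" & records$ref_b == "C" &
                 !is.na(records$rate_a) & !is.na(records$rate_b), ,
               drop = FALSE]
  if (subset == "synonymous")
    r <- r[!is.na(r$synonymous) & r$synonymous, , drop = FALSE]
  else if (subset == "non-synonymous")
    r <- r[!is.na(r$synonymous) & !r$synonymous, , drop = FALSE]
  else if (subset != "all" && "context" %in% names(r))
    r <- r[r$context == subset, , drop = FALSE]
  if (nrow(r) < 3) stop("fewer than 3 paired rates in subset '", subset, "'")
  list(spearman = stats::cor(r$rate_a, r$rate_b, method = "spearman"),
       pearson = stats::cor(r$rate_a, r$rate_b, method = "pearson"),
       n = nrow(r))
}

#' Load the packaged KRA/KOV editing-difference table
#'
#' The twelve homologous protein-coding sites at which the KRA and KOV
#' mitochondrial editomes differ (losses by genomic substitution, new
#' low-rate edits, and highly differential rates), with reference bases,
#' recorded rates, the affected codons, and whether the carrying gene is an
#' intact protein gene or a chimeric-ORF partial copy.
#'
#' @return data.frame ready for [compare_editomes()].
#' @export
kra_kov_sites <- function() {
  path <- system.file("extdata", "kra_kov_editing_sites.tsv",
                      package = "mtrecomb", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
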