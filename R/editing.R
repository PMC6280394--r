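## C-to-U RNA editing: per-site editing extent from stranded base counts,
## threshold-based site calling, genomic-context classification and
## codon-level effect annotation. All editing logic sees counts oriented to
## the strand of interest, so editing is always C -> T; minus-strand
## editing (a genomic G > A on the reference plus strand) is re-oriented at
## ingestion.

#' Editing call parameters
#'
#' The calling rule is a conjunction: a site is called edited iff its
#' oriented reference base is C, the editing extent is at least `min_rate`,
#' and at least `min_t_reads` C>T reads were observed.
#'
#' @param min_rate minimum editing extent (default 0.10).
#' @param min_t_reads minimum count of T (edited) reads (default 10).
#' @return A list of class `editing_params`.
#' @export
editing_params <- function(min_rate = 0.10, min_t_reads = 10) {
  stopifnot(min_rate > 0, min_rate <= 1, min_t_reads >= 1)
  structure(list(min_rate = min_rate, min_t_reads = min_t_reads),
            class = "editing_params")
}

#' Editing extent at a site
#'
#' The count of Ts divided by the sum of Cs and Ts; reads of other bases do
#' not enter this statistic.
#'
#' @param c_count,t_count reads supporting C (unedited) and T (edited),
#'   oriented to the strand of interest.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) at zero usable depth.
#' @export
editing_extent <- function(c_count, t_count) {
  depth <- c_count + t_count
  out <- ifelse(depth > 0, t_count / depth, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " site(s) skipped: zero usable (C+T) depth")
  out
}

#' Orient a pileup to the strand of interest
#'
#' For sites whose strand of interest is `-`, complements the reference
#' base and swaps the A/T and C/G counts so that downstream editing logic
#' sees plus-strand-like C>T signals.
#'
#' @param pileup data.frame with columns `molecule`, `pos`, `ref`, `strand`,
#'   `nA`, `nC`, `nG`, `nT` (counts on the reference plus strand).
#' @return The pileup with counts and `ref` oriented to `strand`.
#' @export
orient_pileup <- function(pileup) {
  neg <- pileup$strand == "-"
  if (any(neg)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    pileup$ref[neg] <- comp[pileup$ref[neg]]
    tmp <- pileup[neg, c("nA", "nC", "nG", "nT")]
    pileup$nA[neg] <- tmp$nT; pileup$nT[neg] <- tmp$nA
    pileup$nC[neg] <- tmp$nG; pileup$nG[neg] <- tmp$nC
  }
  pileup
}

#' Call C-to-U editing sites from an oriented pileup
#'
#' Every candidate site is retained in the output with its extent and a
#' `called` flag for audit; sites with oriented C+T depth below 10 are
#' additionally flagged `low_depth` and are excluded from summaries.
#'
#' @param pileup an oriented pileup (see [orient_pileup()]); columns
#'   `molecule`, `pos` (0-based), `ref`, `strand`, `nA`, `nC`, `nG`, `nT`.
#' @param params an [editing_params()] object.
#' @param exclude_kinds feature kinds whose sites are never called
#'   (default rRNA/tRNA, whose coverage is biased by library preparation);
#'   applied only when `features` is supplied.
#' @param features optional molecule-coordinate feature table used for the
#'   exclusion and for context labels (see [classify_context()]).
#' @return data.frame of editing sites: input columns plus `extent`,
#'   `called`, `low_depth`, and `context` when features were given.
#' @export
call_editing_sites <- function(pileup, params = editing_params(),
                               features = NULL,
                               exclude_kinds = c("rRNA", "tRNA")) {
  stopifnot(inherits(params, "editing_params"))
  p <- pileup
  p$extent <- suppressWarnings(editing_extent(p$nC, p$nT))
  p$low_depth <- (p$nC + p$nT) < 10
  p$called <- !is.na(p$extent) & p$ref == "C" &
    p$extent >= params$min_rate & p$nT >= params$min_t_reads
  if (!is.null(features)) {
    p$context <- vapply(seq_len(nrow(p)), function(i)
      classify_context(p$pos[i], features,
                       molecule = p$molecule[i], strand = p$strand[i]), "")
    excl <- excluded_positions(p, features, exclude_kinds)
    p$called[excl] <- FALSE
    p$excluded <- excl
  }
  p
}

excluded_positions <- function(p, features, exclude_kinds) {
  f <- features[features$kind %in% exclude_kinds, , drop = FALSE]
  if (!nrow(f)) return(rep(FALSE, nrow(p)))
  has_mol <- "molecule" %in% names(f)
  vapply(seq_len(nrow(p)), function(i) {
    ff <- if (has_mol) f[f$molecule == p$molecule[i], , drop = FALSE] else f
    any(ff$start <= p$pos[i] & p$pos[i] < ff$end)
  }, TRUE)
}

CONTEXT_PRECEDENCE <- c("CDS", "intron", "UTR", "ORF", "island", "intergenic")

#' Genomic context of a position
#'
#' Assigns the highest-precedence overlapping feature kind:
#' CDS > intron > UTR > ORF > island > intergenic. Stranded kinds must match
#' the query strand; islands are unstranded. Overlapping same-precedence
#' features resolve to the first by (start, id) with a warning.
#'
#' @param pos 0-based position.
#' @param features data.frame with columns `feature_id`, `start`, `end`,
#'   `strand`, `kind` and optionally `molecule`.
#' @param molecule optional molecule id to filter on.
#' @param strand query strand (default `"+"`).
#' @return One of the context labels.
#' @export
classify_context <- function(pos, features, molecule = NULL, strand = "+") {
  f <- features
  if (!is.null(molecule) && "molecule" %in% names(f))
    f <- f[f$molecule == molecule, , drop = FALSE]
  f <- f[f$start <= pos & pos < f$end, , drop = FALSE]
  for (kind in CONTEXT_PRECEDENCE[-length(CONTEXT_PRECEDENCE)]) {
    hit <- f[f$kind == kind, , drop = FALSE]
    if (kind != "island")
      hit <- hit[hit$strand == strand, , drop = FALSE]
    if (nrow(hit) > 1) {
      hit <- hit[order(hit$start, hit$feature_id), , drop = FALSE]
      warning("overlapping ", kind, " features at position ", pos,
              "; using ", hit$feature_id[1])
    }
    if (nrow(hit)) return(kind)
  }
  "intergenic"
}

#' Annotate the codon-level effect of an editing site
#'
#' Given the spliced CDS sequence on the coding strand and the site's
#' 0-based position within it, reports the reference codon, the codon after
#' applying the C-to-T edit, both amino acids (standard genetic code, which
#' plant mitochondria use), the codon position of the edit, and whether the
#' change is synonymous.
#'
#' @param cds_seq spliced CDS nucleotide string, coding strand, length a
#'   multiple of 3.
#' @param pos_in_cds 0-based offset of the edited C within `cds_seq`.
#' @param cds_id label used in error messages.
#' @return A list: `codon_before`, `codon_after`, `aa_before`, `aa_after`,
#'   `codon_position` (1-3), `synonymous`.
#' @export
annotate_effect <- function(cds_seq, pos_in_cds, cds_id = "CDS") {
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n %% 3 != 0)
    stop("CDS length of ", cds_id, " is not a multiple of 3 (", n, ")")
  if (pos_in_cds < 0 || pos_in_cds >= n)
    stop("position outside CDS ", cds_id)
  if (substr(cds_seq, pos_in_cds + 1, pos_in_cds + 1) != "C")
    stop("site in ", cds_id, " is not a C on the coding strand")
  codon_idx <- pos_in_cds %/% 3
  codon_pos <- pos_in_cds %% 3 + 1L
  codon_before <- substr(cds_seq, codon_idx * 3 + 1, codon_idx * 3 + 3)
  codon_after <- codon_before
  substr(codon_after, codon_pos, codon_pos) <- "T"
  aa_before <- unname(Biostrings::GENETIC_CODE[codon_before])
  aa_after <- unname(Biostrings::GENETIC_CODE[codon_after])
  list(codon_before = codon_before, codon_after = codon_after,
       aa_before = aa_before, aa_after = aa_after,
       codon_position = codon_pos, synonymous = aa_before == aa_after)
}

#' Read or write the editing-site pileup TSV dialect
#'
#' On disk, positions are 1-based; in memory they are 0-based. Columns:
#' `molecule`, `pos`, `ref`, `strand`, `nA`, `nC`, `nG`, `nT`.
#'
#' @param path file path.
#' @return `read_pileup()` returns the in-memory data.frame.
#' @export
read_pileup <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule", "pos", "ref", "strand", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(p)))
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  p$pos <- as.integer(p$pos) - 1L
  p
}

#' @rdname read_pileup
#' @param pileup in-memory pileup (0-based `pos`).
#' @export
write_pileup <- function(pileup, path) {
  p <- pileup
  p$pos <- p$pos + 1L
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse samtools-mpileup text into a per-site count pileup
#'
#' Minimal parser for the default 6-column `samtools mpileup` text format
#' (chrom, 1-based pos, ref, depth, read bases, quals): counts `.`/`,` as
#' the reference base and A/C/G/T (either case) as alternatives, skipping
#' indel and read start/end markup. Counts are reported on the reference
#' plus strand; use [orient_pileup()] afterwards.
#'
#' @param path mpileup text file.
#' @param strand strand of interest to record per site (default `"+"`).
#' @return An (unoriented) pileup data.frame.
#' @export
parse_mpileup <- function(path, strand = "+") {
  lines <- readLines(path)
  out <- lapply(strsplit(lines, "\t"), function(fld) {
    if (length(fld) < 5) return(NULL)
    ref <- toupper(fld[3])
    bases <- fld[5]
    ## strip markup: ^X (read start + mapq), $, and +N/-N indel runs
    bases <- gsub("\\^.", "", bases)
    bases <- gsub("\\$", "", bases)
    while (grepl("[+-][0-9]+", bases)) {
      m <- regmatches(bases, regexpr("[+-][0-9]+", bases))[[1]]
      nlen <- as.integer(substr(m, 2, nchar(m)))
      bases <- sub(paste0("[+-][0-9]+[ACGTNacgtn]{", nlen, "}"), "", bases)
    }
    ch <- strsplit(toupper(gsub("[.,]", ref, bases)), "")[[1]]
    data.frame(molecule = fld[1], pos = as.integer(fld[2]) - 1L, ref = ref,
               strand = strand,
               nA = sum(ch == "A"), nC = sum(ch == "C"),
               nG = sum(ch == "G"), nT = sum(ch == "T"))
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
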