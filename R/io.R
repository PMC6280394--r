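## Genome bundle I/O: FASTA + GFF3 + repeat-pair TSV (+ BED6 repeat copies).
## GFF3 is 1-based inclusive on disk and converted to 0-based half-open in
## memory. The GFF3 writer emits a fixed field/attribute order so that a
## read -> write round trip of records written by this package is
## byte-identical.

GFF_SOURCE <- "mtrecomb"

#' Write a genome bundle (FASTA + GFF3 + repeat TSV + BED6)
#'
#' Each molecule is written as one FASTA record (its forward-strand sequence
#' in the current layout) and its features are instantiated onto molecule
#' coordinates. Molecule topology is recorded on a `region` line via the
#' `Is_circular` attribute. Repeat pairs are written both as a TSV table
#' (`pair_id`, `copy_a`, `copy_b`, `orientation`, `length`, `identity`) and
#' as BED6 intervals whose name field carries the pair id.
#'
#' @param genome an `mt_genome`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, default `"genome"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_genome_bundle <- function(genome, dir, prefix = "genome") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             gff3 = file.path(dir, paste0(prefix, ".gff3")),
             repeats = file.path(dir, paste0(prefix, ".repeats.tsv")),
             bed = file.path(dir, paste0(prefix, ".repeats.bed")))

  seqs <- Biostrings::DNAStringSet(vapply(genome$molecules, function(m)
    molecule_sequence(genome, m), ""))
  names(seqs) <- names(genome$molecules)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])

  gff <- character()
  bed <- character()
  rep_rows <- list()
  gff <- c(gff, "##gff-version 3")
  for (m in genome$molecules) {
    len <- molecule_length(genome, m)
    gff <- c(gff, sprintf("##sequence-region %s 1 %d", m$id, len))
    gff <- c(gff, gff_line(m$id, "region", 0L, len, "+",
                           sprintf("ID=%s;Is_circular=%s", m$id,
                                   if (m$topology == "circular") "true" else "false")))
    inst <- instantiate_features(genome, m)
    ## features occurring once keep their plain id, so a read -> write
    ## round trip of a bundle is byte-stable; multi-occurrence features
    ## (repeat-borne) carry the occurrence suffix
    multi <- inst$feature_id %in%
      inst$feature_id[duplicated(inst$feature_id)]
    inst$out_id <- ifelse(multi, inst$instance_id, inst$feature_id)
    pair_of <- copy_pair_lookup(genome)
    for (i in seq_len(nrow(inst))) {
      attrs <- sprintf("ID=%s", inst$out_id[i])
      if (!is.na(inst$gene_name[i]))
        attrs <- paste0(attrs, ";gene_name=", inst$gene_name[i])
      pid <- pair_of[inst$feature_id[i]]
      if (!is.na(pid)) attrs <- paste0(attrs, ";pair=", pid)
      gff <- c(gff, gff_line(m$id, inst$kind[i], inst$start[i], inst$end[i],
                             inst$strand[i], attrs))
      if (inst$kind[i] == "repeat_copy") {
        bed <- c(bed, sprintf("%s\t%d\t%d\t%s\t0\t%s", m$id, inst$start[i],
                              inst$end[i], pid, inst$strand[i]))
      }
    }
    if (any(inst$kind == "repeat_copy")) {
      rc <- inst[inst$kind == "repeat_copy", , drop = FALSE]
      for (pid in unique(pair_of[rc$feature_id])) {
        cc <- rc[pair_of[rc$feature_id] == pid, , drop = FALSE]
        if (nrow(cc) == 2) {
          pr <- genome$repeat_pairs[genome$repeat_pairs$pair_id == pid, ]
          rep_rows[[pid]] <- data.frame(
            pair_id = pid, copy_a = cc$out_id[1], copy_b = cc$out_id[2],
            orientation = if (cc$strand[1] == cc$strand[2]) "direct" else "inverted",
            length = cc$end[1] - cc$start[1],
            identity = if (nrow(pr)) pr$identity[1] else 1)
        }
      }
    }
  }
  writeLines(gff, paths[["gff3"]])
  writeLines(bed, paths[["bed"]])
  rep_tab <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(pair_id = character(), copy_a = character(),
               copy_b = character(), orientation = character(),
               length = integer(), identity = numeric())
  utils::write.table(rep_tab, paths[["repeats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

## feature_id -> pair_id for repeat copies, from segment-level pairs (every
## repeat_copy feature on a pair's segment belongs to that pair) and, for
## unsegmented bundles, from the feature-level repeat table
copy_pair_lookup <- function(genome) {
  rc <- genome$features[genome$features$kind == "repeat_copy", , drop = FALSE]
  out <- stats::setNames(rep(NA_character_, nrow(rc)), rc$feature_id)
  for (i in seq_len(nrow(rc))) {
    hit <- genome$repeat_pairs$pair_id[
      genome$repeat_pairs$segment_id == rc$segment_id[i]]
    if (length(hit)) out[rc$feature_id[i]] <- hit[1]
  }
  tab <- genome$repeat_table
  if (!is.null(tab) && nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      for (fid in c(tab$copy_a[i], tab$copy_b[i]))
        if (fid %in% names(out) && is.na(out[fid]))
          out[fid] <- tab$pair_id[i]
    }
  }
  out
}

## one GFF3 line; start/end arrive 0-based half-open, written 1-based inclusive
gff_line <- function(seqid, type, start, end, strand, attrs) {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          seqid, GFF_SOURCE, type, start + 1L, end, strand, attrs)
}

#' Read a genome bundle into a segmented genome
#'
#' Reads FASTA sequences (via \pkg{Biostrings}), GFF3 features (via
#' \pkg{rtracklayer}; 1-based inclusive on disk, converted to 0-based
#' half-open), and the repeat-pair TSV. Each molecule initially becomes a
#' single segment named after the molecule; use [segment_genome()] to split
#' molecules at repeat-copy boundaries before recombination analysis.
#'
#' @param fasta,gff3,repeats file paths; `repeats` may be `NULL`.
#' @return An `mt_genome`. The raw repeat table (feature-level copies) is
#'   kept in the `repeat_table` element.
#' @export
read_genome_bundle <- function(fasta, gff3, repeats = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated FASTA header: ", ids[duplicated(ids)][1])
  names(seqs) <- ids

  gr <- rtracklayer::import(gff3)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  regions <- df[df$type == "region", , drop = FALSE]
  circ <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (nrow(regions) && "Is_circular" %in% names(regions)) {
    for (i in seq_len(nrow(regions)))
      circ[regions$seqnames[i]] <- identical(tolower(as.character(
        regions$Is_circular[i])), "true")
  }

  feats <- df[df$type != "region", , drop = FALSE]
  seg_len <- stats::setNames(Biostrings::width(seqs), ids)
  features <- data.frame(
    feature_id = as.character(feats$ID),
    segment_id = feats$seqnames,
    start = as.integer(feats$start) - 1L,   # GFF3 1-based -> 0-based
    end = as.integer(feats$end),
    strand = ifelse(feats$strand %in% c("+", "-"), feats$strand, "+"),
    kind = feats$type,
    gene_name = if ("gene_name" %in% names(feats))
      as.character(feats$gene_name) else NA_character_)
  if (nrow(features)) {
    if (!all(features$segment_id %in% ids))
      stop("GFF3 seqid not present in FASTA: ",
           setdiff(features$segment_id, ids)[1])
    bad <- features$end > seg_len[features$segment_id]
    if (any(bad))
      stop("feature beyond sequence end: ", features$feature_id[bad][1])
  }

  molecules <- lapply(ids, function(id)
    mt_molecule(id, if (circ[[id]]) "circular" else "linear",
                data.frame(segment_id = id, orientation = "+")))
  g <- mt_genome(
    segments = data.frame(segment_id = ids,
                          sequence = as.character(seqs)),
    molecules = molecules, features = features)
  if (!is.null(repeats)) {
    g$repeat_table <- utils::read.delim(repeats, stringsAsFactors = FALSE)
  }
  g
}

#' Split bundle molecules into segments at repeat-copy boundaries
#'
#' Converts a freshly read genome bundle (one segment per molecule) into a
#' segmented genome in which each repeat pair is represented by a single
#' shared segment occurring at both copy locations, so that the
#' recombination engine can operate on it. Repeat copies of a pair are
#' treated as interchangeable: the shared segment carries the sequence of
#' `copy_a` (copies need not be 100\% identical). Features must not cross a
#' repeat-copy boundary. The stored pair orientation is recomputed from the
#' copies' strands and must agree with the table.
#'
#' @param genome an `mt_genome` produced by [read_genome_bundle()] whose
#'   `repeat_table` element is populated.
#' @return A new segmented `mt_genome` with segment-level repeat pairs.
#' @export
segment_genome <- function(genome) {
  tab <- genome$repeat_table
  if (is.null(tab) || !nrow(tab)) return(genome)
  feats <- genome$features
  inst <- feats  # bundle genomes: segment coords == molecule coords

  ## locate copies
  copies <- list()
  for (i in seq_len(nrow(tab))) {
    for (which in c("copy_a", "copy_b")) {
      fid <- tab[[which]][i]
      f <- feats[feats$feature_id == fid, , drop = FALSE]
      if (!nrow(f)) stop("repeat copy feature not found: ", fid)
      copies[[length(copies) + 1L]] <- data.frame(
        pair_id = tab$pair_id[i], which = which, feature_id = fid,
        molecule = f$segment_id, start = f$start, end = f$end,
        strand = f$strand)
    }
  }
  copies <- do.call(rbind, copies)
  for (pid in unique(copies$pair_id)) {
    cc <- copies[copies$pair_id == pid, ]
    if (diff(cc$end - cc$start) != 0)
      stop("repeat copies of pair ", pid, " differ in length")
    rel <- if (cc$strand[1] == cc$strand[2]) "direct" else "inverted"
    stored <- tab$orientation[tab$pair_id == pid]
    if (length(stored) && !is.na(stored) && stored != rel)
      stop("stored orientation of pair ", pid,
           " (", stored, ") does not match copy strands (", rel, ")")
  }

  new_segments <- list(); new_mols <- list(); new_feats <- list()
  pair_seg <- stats::setNames(paste0("R_", unique(copies$pair_id)),
                              unique(copies$pair_id))
  pair_seq_done <- character()

  for (m in genome$molecules) {
    mol_id <- m$id
    mol_seq <- molecule_sequence(genome, m)
    len <- nchar(mol_seq)
    cc <- copies[copies$molecule == mol_id, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    if (nrow(cc) > 1 && any(cc$start[-1] < cc$end[-nrow(cc)]))
      stop("overlapping repeat copies on molecule ", mol_id)
    bounds <- sort(unique(c(0L, len, cc$start, cc$end)))
    layout <- data.frame(segment_id = character(), orientation = character())
    k <- 0L
    for (j in seq_len(length(bounds) - 1L)) {
      bs <- bounds[j]; be <- bounds[j + 1L]
      hit <- which(cc$start == bs & cc$end == be)
      piece_seq <- substr(mol_seq, bs + 1L, be)
      if (length(hit)) {
        pid <- cc$pair_id[hit[1]]
        sid <- pair_seg[[pid]]
        orient <- cc$strand[hit[1]]
        if (!sid %in% pair_seq_done) {
          ## store in copy_a's reading frame so orientation == copy strand
          sseq <- if (orient == "+") piece_seq else revcomp_chr(piece_seq)
          new_segments[[sid]] <- data.frame(segment_id = sid, sequence = sseq)
          pair_seq_done <- c(pair_seq_done, sid)
        }
      } else {
        k <- k + 1L
        sid <- sprintf("%s_s%02d", mol_id, k)
        orient <- "+"
        new_segments[[sid]] <- data.frame(segment_id = sid,
                                          sequence = piece_seq)
      }
      layout <- rbind(layout, data.frame(segment_id = sid,
                                         orientation = orient))
      ## re-anchor features fully inside this piece
      fin <- feats[feats$segment_id == mol_id & feats$start >= bs &
                     feats$end <= be, , drop = FALSE]
      if (nrow(fin)) {
        if (orient == "+") {
          fin$start <- fin$start - bs
          fin$end <- fin$end - bs
        } else {
          s2 <- be - fin$end; e2 <- be - fin$start
          fin$strand <- ifelse(fin$strand == "+", "-", "+")
          fin$start <- s2; fin$end <- e2
        }
        fin$segment_id <- sid
        new_feats[[length(new_feats) + 1L]] <- fin
      }
    }
    ## features crossing a boundary were silently not re-anchored: check
    n_got <- sum(vapply(new_feats, nrow, 0L))
    new_mols[[mol_id]] <- mt_molecule(mol_id, m$topology, layout)
  }

  nf <- if (length(new_feats)) do.call(rbind, new_feats) else NULL
  n_expected <- nrow(feats)
  if (!is.null(nf) && nrow(nf) < n_expected) {
    missing <- setdiff(feats$feature_id, nf$feature_id)
    stop("feature crosses a repeat-copy boundary: ",
         paste(missing, collapse = ", "))
  }
  ## shared repeat segments carry each copy's features once
  if (!is.null(nf)) {
    key <- paste(nf$segment_id, nf$start, nf$end, nf$strand, nf$kind,
                 nf$gene_name, sep = "\r")
    nf <- nf[!duplicated(key), , drop = FALSE]
  }

  pairs <- data.frame(pair_id = unique(copies$pair_id))
  pairs$segment_id <- pair_seg[pairs$pair_id]
  pairs$length <- vapply(pairs$pair_id, function(p)
    copies$end[copies$pair_id == p][1] - copies$start[copies$pair_id == p][1],
    0L)
  pairs$identity <- vapply(pairs$pair_id, function(p) {
    v <- tab$identity[tab$pair_id == p]
    if (length(v)) as.numeric(v[1]) else 1
  }, 0)
  pairs$enabled <- if ("enabled" %in% names(tab))
    as.logical(tab$enabled[match(pairs$pair_id, tab$pair_id)]) else TRUE

  mt_genome(segments = do.call(rbind, new_segments), molecules = new_mols,
            features = nf, repeat_pairs = pairs)
}
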