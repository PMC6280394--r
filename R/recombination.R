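## Repeat-mediated homologous recombination: inversion across inverted
## repeats, excision/integration across direct repeats, breadth-first
## enumeration of reachable genome configurations, and the transcriptional
## context (driving promoter) of genes in each configuration.
##
## Double-stranded circles have no intrinsic orientation, so molecules are
## compared up to rotation AND strand flip; that quotient is what makes the
## two excision routes of an alternating two-pair circle a single state.

#' Construct a genome configuration
#'
#' A configuration is a multiset of molecules (each an ordered list of
#' oriented segments) plus the provenance of recombination moves applied
#' from the initial state. The multiset of segment occurrences, ignoring
#' orientation, is invariant under every recombination move.
#'
#' @param molecules list of `mt_molecule` objects.
#' @param provenance character vector of moves applied so far.
#' @return An object of class `mt_config`.
#' @export
mt_config <- function(molecules, provenance = character()) {
  structure(list(molecules = molecules, provenance = provenance),
            class = "mt_config")
}

#' Initial configuration of a genome (its molecules as annotated)
#' @param genome an `mt_genome`.
#' @return An `mt_config`.
#' @export
initial_config <- function(genome) {
  mt_config(unname(genome$molecules))
}

#' @export
print.mt_config <- function(x, ...) {
  cat(sprintf("<mt_config> %d molecule(s)%s\n", length(x$molecules),
              if (length(x$provenance))
                paste0(" [", paste(x$provenance, collapse = " > "), "]")
              else ""))
  for (m in x$molecules) print(m)
  invisible(x)
}

## reverse the layout and flip every orientation (read the other strand)
revflip_layout <- function(layout) {
  out <- layout[rev(seq_len(nrow(layout))), , drop = FALSE]
  out$orientation <- ifelse(out$orientation == "+", "-", "+")
  rownames(out) <- NULL
  out
}

rotate_layout <- function(layout, k) {
  n <- nrow(layout)
  if (n == 1L || k %% n == 0L) { rownames(layout) <- NULL; return(layout) }
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  out <- layout[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical form of a molecule
#'
#' For circular molecules, returns the lexicographically least token string
#' over all rotations of the layout and of its strand-flipped reverse; for
#' linear molecules, the least of the layout and its flip. Idempotent. Two
#' molecules represent the same double-stranded DNA iff their canonical
#' forms are identical.
#'
#' @param molecule an `mt_molecule`.
#' @return An `mt_molecule` in canonical form, with the canonical key in
#'   attribute `key`.
#' @export
canonicalize <- function(molecule) {
  lay <- molecule$layout
  cands <- list()
  if (molecule$topology == "circular") {
    for (base in list(lay, revflip_layout(lay)))
      for (k in seq_len(nrow(base)) - 1L)
        cands[[length(cands) + 1L]] <- rotate_layout(base, k)
  } else {
    cands <- list(lay, revflip_layout(lay))
  }
  keys <- vapply(cands, function(l) paste(layout_tokens(l), collapse = " "),
                 "")
  best <- cands[[order(keys)[1]]]
  out <- mt_molecule(molecule$id, molecule$topology, best)
  attr(out, "key") <- min(keys)
  out
}

molecule_key <- function(molecule) {
  k <- attr(molecule, "key")
  if (is.null(k)) k <- attr(canonicalize(molecule), "key")
  paste0(substr(molecule$topology, 1, 1), ":", k)
}

#' Canonical key of a configuration
#'
#' Canonicalizes every molecule and joins the sorted molecule keys; two
#' configurations with equal keys are the same genome state.
#' @param config an `mt_config`.
#' @return A character scalar.
#' @export
config_key <- function(config) {
  paste(sort(vapply(config$molecules, molecule_key, "")), collapse = " | ")
}

canonicalize_config <- function(config) {
  mols <- lapply(config$molecules, canonicalize)
  keys <- vapply(mols, molecule_key, "")
  mols <- mols[order(keys)]
  for (i in seq_along(mols)) mols[[i]]$id <- sprintf("m%d", i)
  mt_config(mols, config$provenance)
}

## rows (mol, pos, orientation) of the pair's segment occurrences
find_copies <- function(config, segment_id) {
  out <- list()
  for (i in seq_along(config$molecules)) {
    lay <- config$molecules[[i]]$layout
    hit <- which(lay$segment_id == segment_id)
    for (p in hit)
      out[[length(out) + 1L]] <- data.frame(mol = i, pos = p,
                                            orientation = lay$orientation[p])
  }
  if (!length(out)) return(data.frame(mol = integer(), pos = integer(),
                                      orientation = character()))
  do.call(rbind, out)
}

resolve_pair <- function(genome, pair) {
  if (is.character(pair)) {
    row <- genome$repeat_pairs[genome$repeat_pairs$pair_id == pair, ]
    if (!nrow(row)) stop("unknown repeat pair: ", pair)
    return(row[1, ])
  }
  pair
}

#' Invert the region between the copies of an inverted repeat pair
#'
#' Models homologous recombination across an inverted repeat pair located on
#' one molecule: the segment order and orientations of one inter-copy arc
#' are reversed and flipped; the molecule count is unchanged. Applying the
#' move twice restores the canonical original, and choosing the other arc
#' yields the same canonical molecule.
#'
#' @param genome an `mt_genome` (for pair lookup).
#' @param config an `mt_config`.
#' @param pair a pair id or a row of `genome$repeat_pairs`.
#' @return The resulting `mt_config` (canonicalized).
#' @export
invert_across <- function(genome, config, pair) {
  pair <- resolve_pair(genome, pair)
  cp <- find_copies(config, pair$segment_id)
  if (nrow(cp) != 2 || cp$mol[1] != cp$mol[2])
    stop("move not applicable: copies of ", pair$pair_id,
         " are not co-located on one molecule")
  if (cp$orientation[1] == cp$orientation[2])
    stop("move not applicable: pair ", pair$pair_id,
         " is in direct orientation (excision applies)")
  m <- config$molecules[[cp$mol[1]]]
  i <- min(cp$pos); j <- max(cp$pos)
  lay <- m$layout
  arc <- if (j - i > 1) lay[(i + 1):(j - 1), , drop = FALSE] else
    lay[0, , drop = FALSE]
  new_lay <- rbind(lay[seq_len(i), , drop = FALSE],
                   revflip_layout(arc),
                   lay[j:nrow(lay), , drop = FALSE])
  mols <- config$molecules
  mols[[cp$mol[1]]] <- mt_molecule(m$id, m$topology, new_lay)
  canonicalize_config(mt_config(mols, c(config$provenance,
                                        paste0("invert:", pair$pair_id))))
}

#' Excise a circle across a direct repeat pair
#'
#' Models homologous recombination across a direct repeat pair on one
#' circular molecule: the molecule resolves into two circles, each carrying
#' exactly one repeat copy; segment content is conserved.
#'
#' @inheritParams invert_across
#' @return The resulting `mt_config` (canonicalized).
#' @export
excise_across <- function(genome, config, pair) {
  pair <- resolve_pair(genome, pair)
  cp <- find_copies(config, pair$segment_id)
  if (nrow(cp) != 2 || cp$mol[1] != cp$mol[2])
    stop("move not applicable: copies of ", pair$pair_id,
         " are not co-located on one molecule")
  if (cp$orientation[1] != cp$orientation[2])
    stop("move not applicable: pair ", pair$pair_id,
         " is in inverted orientation (inversion applies)")
  m <- config$molecules[[cp$mol[1]]]
  if (m$topology != "circular")
    stop("excision is modelled on circular molecules only")
  i <- min(cp$pos); j <- max(cp$pos)
  lay <- m$layout
  arc1 <- if (j - i > 1) lay[(i + 1):(j - 1), , drop = FALSE] else
    lay[0, , drop = FALSE]
  arc2_idx <- c(if (j < nrow(lay)) (j + 1):nrow(lay), if (i > 1) 1:(i - 1))
  arc2 <- lay[arc2_idx, , drop = FALSE]
  mol1 <- mt_molecule(paste0(m$id, ".a"), "circular",
                      rbind(lay[i, , drop = FALSE], arc1))
  mol2 <- mt_molecule(paste0(m$id, ".b"), "circular",
                      rbind(lay[j, , drop = FALSE], arc2))
  mols <- c(config$molecules[-cp$mol[1]], list(mol1, mol2))
  canonicalize_config(mt_config(mols, c(config$provenance,
                                        paste0("excise:", pair$pair_id))))
}

#' Integrate two circles across a repeat pair
#'
#' Inverse of [excise_across()] up to canonical form: the two circular
#' molecules each carrying one copy of the pair are merged into one circle
#' in which the copies are directly oriented.
#'
#' @inheritParams invert_across
#' @return The resulting `mt_config` (canonicalized).
#' @export
integrate_across <- function(genome, config, pair) {
  pair <- resolve_pair(genome, pair)
  cp <- find_copies(config, pair$segment_id)
  if (nrow(cp) != 2)
    stop("move not applicable: pair ", pair$pair_id,
         " does not have exactly two copies (", nrow(cp), " found)")
  if (cp$mol[1] == cp$mol[2])
    stop("move not applicable: copies of ", pair$pair_id,
         " are already co-located")
  m1 <- config$molecules[[cp$mol[1]]]
  m2 <- config$molecules[[cp$mol[2]]]
  if (m1$topology != "circular" || m2$topology != "circular")
    stop("integration is modelled on circular molecules only")
  l1 <- rotate_layout(m1$layout, cp$pos[1] - 1L)
  l2 <- m2$layout
  if (cp$orientation[1] != cp$orientation[2]) {
    l2 <- revflip_layout(l2)
  }
  p2 <- which(l2$segment_id == pair$segment_id)[1]
  l2 <- rotate_layout(l2, p2 - 1L)
  merged <- mt_molecule(paste0(m1$id, "+", m2$id), "circular", rbind(l1, l2))
  mols <- c(config$molecules[-c(cp$mol)], list(merged))
  canonicalize_config(mt_config(mols, c(config$provenance,
                                        paste0("integrate:", pair$pair_id))))
}

## pairs eligible for moves under the identity threshold / disable flag
eligible_pairs <- function(genome, min_identity = 0.94) {
  rp <- genome$repeat_pairs
  rp[rp$enabled & rp$identity >= min_identity, , drop = FALSE]
}

applicable_moves <- function(genome, config, min_identity = 0.94) {
  rp <- eligible_pairs(genome, min_identity)
  out <- list()
  for (i in seq_len(nrow(rp))) {
    cp <- find_copies(config, rp$segment_id[i])
    if (nrow(cp) != 2) next
    if (cp$mol[1] == cp$mol[2]) {
      same <- cp$orientation[1] == cp$orientation[2]
      topo <- config$molecules[[cp$mol[1]]]$topology
      if (!same) {
        out[[length(out) + 1L]] <- list(kind = "invert", pair = rp[i, ])
      } else if (topo == "circular") {
        out[[length(out) + 1L]] <- list(kind = "excise", pair = rp[i, ])
      }
    } else if (config$molecules[[cp$mol[1]]]$topology == "circular" &&
               config$molecules[[cp$mol[2]]]$topology == "circular") {
      out[[length(out) + 1L]] <- list(kind = "integrate", pair = rp[i, ])
    }
  }
  out
}

apply_move <- function(genome, config, move) {
  switch(move$kind,
         invert = invert_across(genome, config, move$pair),
         excise = excise_across(genome, config, move$pair),
         integrate = integrate_across(genome, config, move$pair))
}

#' Enumerate all genome configurations reachable by recombination
#'
#' Breadth-first closure of the initial configuration under all applicable
#' single recombination moves (inversion across inverted pairs, excision
#' across direct pairs, integration across split pairs). States are stored
#' once by canonical key, and the output is sorted by key, so the result is
#' independent of move application order.
#'
#' @param genome a segmented `mt_genome` with repeat pairs annotated.
#' @param initial optional starting `mt_config`; defaults to
#'   [initial_config()].
#' @param max_states guard against runaway closures (default 10000).
#' @param min_identity minimum repeat identity for a pair to recombine
#'   (default 0.94).
#' @return An object of class `mt_statespace`: list with `states` (named
#'   list of canonical `mt_config`s), `initial_key`, and `edges`
#'   (data.frame from, move, to).
#' @export
enumerate_states <- function(genome, initial = NULL, max_states = 10000,
                             min_identity = 0.94) {
  stopifnot(max_states > 0)
  if (is.null(initial)) initial <- initial_config(genome)
  start <- canonicalize_config(initial)
  seen <- stats::setNames(list(start), config_key(start))
  queue <- list(start)
  edges <- list()
  while (length(queue)) {
    cfg <- queue[[1]]; queue <- queue[-1]
    from_key <- config_key(cfg)
    for (mv in applicable_moves(genome, cfg, min_identity)) {
      nxt <- apply_move(genome, cfg, mv)
      key <- config_key(nxt)
      edges[[length(edges) + 1L]] <- data.frame(
        from = from_key, move = paste0(mv$kind, ":", mv$pair$pair_id),
        to = key)
      if (!key %in% names(seen)) {
        if (length(seen) >= max_states)
          stop("state closure exceeds max_states = ", max_states,
               " (frontier size ", length(queue) + 1L, ")")
        seen[[key]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  seen <- seen[order(names(seen))]
  structure(list(states = seen, initial_key = config_key(start),
                 edges = if (length(edges)) unique(do.call(rbind, edges))
                 else data.frame(from = character(), move = character(),
                                 to = character())),
            class = "mt_statespace")
}

#' @export
print.mt_statespace <- function(x, ...) {
  nmol <- vapply(x$states, function(s) length(s$molecules), 0L)
  cat(sprintf("<mt_statespace> %d state(s): %s\n", length(x$states),
              paste(sprintf("%d with %d molecule(s)",
                            as.integer(table(nmol)),
                            as.integer(names(table(nmol)))),
                    collapse = ", ")))
  invisible(x)
}

## ---- transcription context ----------------------------------------------

## Merge abutting same-gene same-strand instances into gene copies; a copy
## spanning several segments (e.g. a 5' repeat part plus its 3'
## continuation) counts as one gene copy. Adjacency wraps the origin on
## circular molecules. `pos5` is the transcription-start-side coordinate of
## the merged copy (start of the first part on "+", end of the last part on
## "-"; chains are built left to right).
gene_instances <- function(inst, len = NULL, circular = FALSE) {
  g <- inst[!is.na(inst$gene_name) & inst$kind %in%
              c("gene", "CDS", "ORF"), , drop = FALSE]
  empty <- data.frame(copy_id = character(), gene_name = character(),
                      start = integer(), end = integer(),
                      strand = character(), pos5 = integer(),
                      parts = character())
  if (!nrow(g)) return(empty)
  g <- g[order(g$start, g$instance_id), , drop = FALSE]
  n <- nrow(g)
  nxt <- rep(NA_integer_, n)
  has_in <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tgt <- g$end[i]
    if (circular && !is.null(len) && tgt == len) tgt <- 0L
    cand <- which(g$gene_name == g$gene_name[i] & g$strand == g$strand[i] &
                    g$start == tgt & seq_len(n) != i)
    if (length(cand) && !has_in[cand[1]]) {
      nxt[i] <- cand[1]
      has_in[cand[1]] <- TRUE
    }
  }
  starts <- which(!has_in)
  if (!length(starts)) starts <- 1L  # whole-circle gene: break arbitrarily
  out <- list()
  for (s in starts) {
    members <- s
    while (!is.na(nxt[members[length(members)]]) &&
           !nxt[members[length(members)]] %in% members)
      members <- c(members, nxt[members[length(members)]])
    first <- members[1]; last <- members[length(members)]
    pos5 <- if (g$strand[first] == "+") g$start[first] else g$end[last]
    out[[length(out) + 1L]] <- data.frame(
      copy_id = paste0(g$gene_name[first], "#", g$start[first] + 1L),
      gene_name = g$gene_name[first],
      start = g$start[first], end = g$end[last],
      strand = g$strand[first], pos5 = pos5,
      parts = paste(g$feature_id[members], collapse = ","))
  }
  do.call(rbind, out)
}

#' Transcription units of a molecule in a given layout
#'
#' A transcription unit is a promoter plus the ordered features downstream
#' of it on the same strand, up to the next promoter (or terminator, or
#' molecule end; for circular molecules the scan wraps). Gene parts that
#' abut (a repeat-borne 5' part followed by its 3' continuation) are merged
#' into single gene copies before assignment.
#'
#' @param genome an `mt_genome`.
#' @param molecule an `mt_molecule` (typically from an enumerated state).
#' @return data.frame with one row per (promoter, member): `promoter_id`,
#'   `promoter_gene`, `member`, `gene_name`, `rank` (1 = nearest
#'   downstream), `start`, `end`, `strand`.
#' @export
transcription_units <- function(genome, molecule) {
  inst <- instantiate_features(genome, molecule)
  len <- molecule_length(genome, molecule)
  genes <- gene_instances(inst, len, molecule$topology == "circular")
  prom <- inst[inst$kind == "promoter", , drop = FALSE]
  term <- inst[inst$kind == "terminator", , drop = FALSE]
  rows <- list()
  for (strand in c("+", "-")) {
    els <- rbind(
      if (nrow(prom[prom$strand == strand, ]))
        data.frame(id = prom$instance_id[prom$strand == strand],
                   gene = prom$gene_name[prom$strand == strand],
                   pos5 = if (strand == "+")
                     prom$start[prom$strand == strand] else
                       prom$end[prom$strand == strand],
                   type = "promoter",
                   start = prom$start[prom$strand == strand],
                   end = prom$end[prom$strand == strand]),
      if (nrow(term[term$strand == strand, ]))
        data.frame(id = term$instance_id[term$strand == strand],
                   gene = term$gene_name[term$strand == strand],
                   pos5 = if (strand == "+")
                     term$start[term$strand == strand] else
                       term$end[term$strand == strand],
                   type = "terminator",
                   start = term$start[term$strand == strand],
                   end = term$end[term$strand == strand]),
      if (nrow(genes[genes$strand == strand, ]))
        data.frame(id = genes$copy_id[genes$strand == strand],
                   gene = genes$gene_name[genes$strand == strand],
                   pos5 = genes$pos5[genes$strand == strand],
                   type = "gene",
                   start = genes$start[genes$strand == strand],
                   end = genes$end[genes$strand == strand]))
    if (is.null(els) || !nrow(els)) next
    ## order in the direction of transcription
    ord <- if (strand == "+") order(els$pos5, els$id) else
      order(-els$pos5, els$id)
    els <- els[ord, , drop = FALSE]
    n <- nrow(els)
    circular <- molecule$topology == "circular"
    for (p in which(els$type == "promoter")) {
      rank <- 0L
      steps <- if (circular) n - 1L else
        (if (strand == "+") n - p else n - p)
      idx <- p
      for (s in seq_len(if (circular) n - 1L else n - p)) {
        idx <- if (circular) (idx %% n) + 1L else idx + 1L
        if (els$type[idx] %in% c("promoter", "terminator")) break
        if (els$type[idx] == "gene") {
          rank <- rank + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            promoter_id = els$id[p], promoter_gene = els$gene[p],
            member = els$id[idx], gene_name = els$gene[idx], rank = rank,
            start = els$start[idx], end = els$end[idx], strand = strand)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(promoter_id = character(), promoter_gene = character(),
                      member = character(), gene_name = character(),
                      rank = integer(), start = integer(), end = integer(),
                      strand = character()))
  do.call(rbind, rows)
}

#' Which promoter drives a gene copy in a configuration?
#'
#' Scans every molecule of the configuration for copies of the gene and
#' reports the promoter (nearest upstream on the gene's strand, wrapping on
#' circles) whose transcription unit contains each copy.
#'
#' @param genome an `mt_genome`.
#' @param config an `mt_config`.
#' @param gene_name gene to look up.
#' @return data.frame with one row per gene copy: `molecule`, `copy_id`,
#'   `full` (TRUE when the copy includes all annotated parts of the gene,
#'   i.e. has the maximum part count across copies), `promoter_id`,
#'   `promoter_gene` (NA and `"no-promoter"` when none is upstream on a
#'   linear molecule), `rank_in_unit`.
#' @export
transcription_context <- function(genome, config, gene_name) {
  out <- list()
  for (m in config$molecules) {
    inst <- instantiate_features(genome, m)
    genes <- gene_instances(inst, molecule_length(genome, m),
                            m$topology == "circular")
    gi <- genes[genes$gene_name == gene_name, , drop = FALSE]
    if (!nrow(gi)) next
    units <- transcription_units(genome, m)
    for (i in seq_len(nrow(gi))) {
      hit <- units[units$member == gi$copy_id[i], , drop = FALSE]
      hit <- hit[order(hit$rank), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        molecule = m$id, copy_id = gi$copy_id[i],
        n_parts = lengths(strsplit(gi$parts[i], ",")),
        promoter_id = if (nrow(hit)) hit$promoter_id[1] else NA_character_,
        promoter_gene = if (nrow(hit)) hit$promoter_gene[1] else
          "no-promoter",
        rank_in_unit = if (nrow(hit)) hit$rank[1] else NA_integer_)
    }
  }
  if (!length(out))
    return(data.frame(molecule = character(), copy_id = character(),
                      n_parts = integer(), promoter_id = character(),
                      promoter_gene = character(), rank_in_unit = integer()))
  res <- do.call(rbind, out)
  res$full <- res$n_parts == max(res$n_parts)
  res
}

#' Summarise the transcriptional context of a gene across all states
#'
#' For every enumerated state, reports the number of molecules, whether the
#' full gene copy is driven by its own promoter or another gene's, and the
#' context of partial copies. This is the per-state promoter-assignment
#' table behind questions like "in how many joint configurations is the
#' gene transcribed independently of the chimera?".
#'
#' @param genome a segmented `mt_genome`.
#' @param space an `mt_statespace` from [enumerate_states()].
#' @param gene_name the gene of interest.
#' @return data.frame with columns `state`, `n_molecules`,
#'   `full_promoter_gene`, `partial_promoter_gene` (comma-joined when a
#'   state has several partial copies).
#' @export
context_by_state <- function(genome, space, gene_name) {
  out <- lapply(seq_along(space$states), function(i) {
    cfg <- space$states[[i]]
    ctx <- transcription_context(genome, cfg, gene_name)
    full <- ctx[ctx$full, , drop = FALSE]
    part <- ctx[!ctx$full, , drop = FALSE]
    data.frame(state = names(space$states)[i],
               n_molecules = length(cfg$molecules),
               full_promoter_gene = paste(full$promoter_gene, collapse = ","),
               partial_promoter_gene = paste(part$promoter_gene,
                                             collapse = ","))
  })
  do.call(rbind, out)
}

#' Write a configuration report (JSON + TSV summary)
#'
#' The JSON report lists every state's molecules, layouts and canonical
#' keys, plus the per-gene promoter assignment per state; the TSV summary
#' is one row per (state, gene copy).
#'
#' @param genome a segmented `mt_genome`.
#' @param space an `mt_statespace`.
#' @param genes character vector of gene names to report on.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return Invisibly, the summary data.frame.
#' @export
write_config_report <- function(genome, space, genes, json_path = NULL,
                                tsv_path = NULL) {
  summary_rows <- list()
  states <- lapply(seq_along(space$states), function(i) {
    cfg <- space$states[[i]]
    key <- names(space$states)[i]
    assign <- list()
    for (g in genes) {
      ctx <- transcription_context(genome, cfg, g)
      for (j in seq_len(nrow(ctx))) {
        summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
          state = sprintf("S%d", i), gene = g, copy = ctx$copy_id[j],
          full = ctx$full[j], promoter_gene = ctx$promoter_gene[j])
      }
      assign[[g]] <- ctx
    }
    list(id = sprintf("S%d", i), key = key,
         n_molecules = length(cfg$molecules),
         molecules = lapply(cfg$molecules, function(m)
           list(id = m$id, topology = m$topology,
                layout = layout_tokens(m$layout))),
         promoter_assignment = assign)
  })
  smry <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(state = character(), gene = character(), copy = character(),
               full = logical(), promoter_gene = character())
  if (!is.null(json_path))
    jsonlite::write_json(list(initial = space$initial_key, states = states),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(smry, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(smry)
}
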