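## End-to-end orchestration from a YAML config: genome/recombination report,
## editing calls, editome comparison, coverage islands and fold changes,
## with a manifest recording parameters and input checksums. Outputs are
## deterministic for identical (inputs, config, seed).

#' Load and validate a pipeline run configuration
#'
#' The configuration is a single YAML file. Every referenced input file
#' must exist before anything runs; parameter blocks are validated against
#' their type invariants. Defaults equal the established analysis
#' parameters: editing call 10\% and 10 reads, comparison bounds 0.8/0.3,
#' residual activity 0.1\%, 100-bp windows, 12000 reads per merged window.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A validated config list of class `mt_run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "mtrecomb_out"
  ## collect referenced files and check existence up front
  paths <- c(cfg$genome$fasta, cfg$genome$gff3, cfg$genome$repeats,
             cfg$editing$pileup, cfg$compare$map, cfg$compare$a,
             cfg$compare$b, cfg$coverage$windows, cfg$coverage$gene_mask,
             cfg$coverage$counts, cfg$coverage$sample_sheet)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("config error: missing input file(s): ",
         paste(missing, collapse = ", "))
  ## materialise parameter blocks (validates invariants)
  cfg$editing_params <- do.call(editing_params,
                                cfg$editing$params %||% list())
  th <- cfg$compare$thresholds %||% list()
  th$call <- cfg$editing_params
  cfg$comparison_thresholds <- do.call(comparison_thresholds, th)
  cfg$island_params <- do.call(island_params,
                               cfg$coverage$island %||% list())
  class(cfg) <- "mt_run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: (1) genome loading (bundle paths or the
#' built-in synthetic toy genome), repeat segmentation, configuration
#' enumeration and the per-state promoter report; (2) editing-site calling
#' from a pileup TSV; (3) editome comparison over a homologous-site map;
#' (4) coverage TPM normalisation, island detection and gender fold
#' changes. Any stage failure aborts with the stage name. A
#' `manifest.json` in the output directory records the package version,
#' all parameters, the seed, and md5 checksums of the inputs.
#'
#' @param config path to a YAML config or a list (see
#'   [load_run_config()]).
#' @return Invisibly, a list of stage results.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "mt_run_config")) config else
    load_run_config(config)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- genome / recombination ----
  if (!is.null(cfg$genome)) {
    res$genome <- stage("genome", {
      if (identical(cfg$genome$synthetic, "toy")) {
        build_toy_genome(seed = cfg$seed)$genome
      } else {
        g <- read_genome_bundle(cfg$genome$fasta, cfg$genome$gff3,
                                cfg$genome$repeats)
        segment_genome(g)
      }
    })
    res$states <- stage("recombination", {
      enumerate_states(res$genome,
                       max_states = cfg$recombination$max_states %||% 10000,
                       min_identity = cfg$recombination$min_identity %||%
                         0.94)
    })
    genes <- cfg$recombination$genes %||% "cob"
    stage("recombination", write_config_report(
      res$genome, res$states, genes,
      json_path = file.path(out_dir, "configurations.json"),
      tsv_path = file.path(out_dir, "configurations.tsv")))
  }

  ## ---- editing ----
  if (!is.null(cfg$editing)) {
    res$editing <- stage("editing", {
      p <- orient_pileup(read_pileup(cfg$editing$pileup))
      call_editing_sites(p, cfg$editing_params)
    })
    stage("editing", {
      tab <- res$editing
      tab$pos <- tab$pos + 1L  # report files are 1-based
      utils::write.table(tab, file.path(out_dir, "editing_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  ## ---- editome comparison ----
  if (!is.null(cfg$compare)) {
    res$comparison <- stage("compare", {
      map <- utils::read.delim(cfg$compare$map, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
      if (!is.null(cfg$compare$a))
        map <- join_editomes(map,
                             utils::read.delim(cfg$compare$a,
                                               stringsAsFactors = FALSE),
                             utils::read.delim(cfg$compare$b,
                                               stringsAsFactors = FALSE))
      compare_editomes(map, cfg$comparison_thresholds)
    })
    stage("compare", {
      utils::write.table(res$comparison,
                         file.path(out_dir, "editome_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- summarize_comparison(res$comparison)
      jsonlite::write_json(
        list(by_class = as.list(s$by_class), losses_intact = s$losses,
             n = s$n),
        file.path(out_dir, "editome_summary.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }

  ## ---- coverage ----
  if (!is.null(cfg$coverage)) {
    res$coverage <- stage("coverage", {
      out <- list()
      if (!is.null(cfg$coverage$windows)) {
        w <- utils::read.delim(cfg$coverage$windows,
                               stringsAsFactors = FALSE)
        mask <- if (!is.null(cfg$coverage$gene_mask))
          utils::read.delim(cfg$coverage$gene_mask,
                            stringsAsFactors = FALSE) else NULL
        out$islands <- detect_islands(w, mask, cfg$island_params)
        write_islands(out$islands,
                      bed_path = file.path(out_dir, "islands.bed"),
                      tsv_path = file.path(out_dir, "islands.tsv"))
      }
      if (!is.null(cfg$coverage$counts)) {
        cts <- utils::read.delim(cfg$coverage$counts, row.names = 1,
                                 check.names = FALSE)
        lens <- cts$length
        cts$length <- NULL
        tpm <- tpm_normalize(cts, lens)
        utils::write.table(data.frame(feature = rownames(tpm), tpm,
                                      check.names = FALSE),
                           file.path(out_dir, "coverage_tpm.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$tpm <- tpm
        if (!is.null(cfg$coverage$sample_sheet)) {
          sheet <- utils::read.delim(cfg$coverage$sample_sheet,
                                     stringsAsFactors = FALSE)
          long <- data.frame(
            feature = rep(rownames(tpm), ncol(tpm)),
            sample = rep(colnames(tpm), each = nrow(tpm)),
            tpm = as.vector(tpm))
          fc_feats <- cfg$coverage$fold_change_features %||% rownames(tpm)
          out$fold_changes <- do.call(rbind, lapply(fc_feats, function(f) {
            fc <- gender_fold_change(long, sheet, f)
            data.frame(feature = f, ratio = fc$ratio, mean_f = fc$mean_f,
                       mean_h = fc$mean_h, direction = fc$direction,
                       pseudo_count = fc$pseudo_count)
          }))
          utils::write.table(out$fold_changes,
                             file.path(out_dir, "fold_changes.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      out
    })
  }

  ## ---- manifest ----
  inputs <- c(cfg$genome$fasta, cfg$genome$gff3, cfg$genome$repeats,
              cfg$editing$pileup, cfg$compare$map, cfg$compare$a,
              cfg$compare$b, cfg$coverage$windows, cfg$coverage$gene_mask,
              cfg$coverage$counts, cfg$coverage$sample_sheet)
  manifest <- list(
    package = "mtrecomb",
    version = as.character(utils::packageVersion("mtrecomb")),
    seed = cfg$seed,
    parameters = list(
      editing = unclass(cfg$editing_params),
      comparison = lapply(unclass(cfg$comparison_thresholds), unclass),
      islands = unclass(cfg$island_params)),
    inputs = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Join per-haplotype editing tables onto a homologous-site map
#'
#' Fills `rate_a`/`rate_b` from two editing-site tables (as written by the
#' editing stage: 1-based `pos`, `extent`, `called`). A haplotype's rate is
#' recorded at a mapped site only when the site was called edited there;
#' otherwise the rate is missing, meaning the editome has no record.
#'
#' @param map data.frame with `position_a`, `position_b` (1-based) and
#'   optionally `molecule_a`, `molecule_b`.
#' @param sites_a,sites_b editing tables with `pos` (1-based), `extent`,
#'   `called`, optionally `molecule`.
#' @return The map with `rate_a`, `rate_b`, `ref_a`, `ref_b` filled.
#' @export
join_editomes <- function(map, sites_a, sites_b) {
  pick <- function(sites, positions, molecules) {
    vapply(seq_along(positions), function(i) {
      s <- sites[sites$pos == positions[i], , drop = FALSE]
      if (!is.null(molecules) && "molecule" %in% names(s))
        s <- s[s$molecule == molecules[i], , drop = FALSE]
      if (!nrow(s) || !s$called[1]) NA_real_ else s$extent[1]
    }, 0)
  }
  ref_pick <- function(sites, positions, molecules) {
    vapply(seq_along(positions), function(i) {
      s <- sites[sites$pos == positions[i], , drop = FALSE]
      if (!is.null(molecules) && "molecule" %in% names(s))
        s <- s[s$molecule == molecules[i], , drop = FALSE]
      if (!nrow(s)) NA_character_ else s$ref[1]
    }, "")
  }
  map$rate_a <- pick(sites_a, map$position_a, map$molecule_a)
  map$rate_b <- pick(sites_b, map$position_b, map$molecule_b)
  if (!"ref_a" %in% names(map))
    map$ref_a <- ref_pick(sites_a, map$position_a, map$molecule_a)
  if (!"ref_b" %in% names(map))
    map$ref_b <- ref_pick(sites_b, map$position_b, map$molecule_b)
  map
}
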