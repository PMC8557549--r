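#' Build a run configuration for the full analysis
#'
#' @param species A list of per-species input descriptions; each element is a
#'   list with `label` and either `fasta` (path) or `cds` (a CDS tibble), plus
#'   optional `expression` (TSV path, `gene_id<TAB>fpkm`).
#' @param orthologs Optional ortholog mapping for the first two species: a
#'   tibble with `id_a`, `id_b` or a TSV path; or an externally computed
#'   Ka/Ks TSV read with [read_kaks_tsv()] may be passed to
#'   [run_full_analysis()]'s `kaks` argument instead.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all stochastic steps.
#' @param min_length,drop_internal_stops Filtering options ([filter_cds()]).
#' @param fraction,threshold,alpha Optimal-codon options
#'   ([find_optimal_codons()]).
#' @param cor_method Correlation method for every correlation stage.
#' @param n_axes CA axes ([correspondence_analysis()]).
#' @param linkage,distance Clustering options ([cluster_species()]).
#' @param pr2_scope PR2 codon scope.
#' @param digits Decimal places for floats in the TSV outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(species, orthologs = NULL, out_dir = tempfile("codonscope_"),
                       seed = 1L, min_length = 400L, drop_internal_stops = TRUE,
                       fraction = 0.10, threshold = 0.08, alpha = 0.01,
                       cor_method = "spearman", n_axes = 5L,
                       linkage = "average", distance = "euclidean",
                       pr2_scope = "fourfold_only", digits = 4L) {
  abort_if(length(species) < 1, "at least one species input is required")
  for (sp in species) {
    abort_if(is.null(sp$label), "every species entry needs a `label`")
    abort_if(is.null(sp$fasta) && is.null(sp$cds),
             "every species entry needs `fasta` or `cds`")
    if (!is.null(sp$fasta)) {
      abort_if(!file.exists(sp$fasta), paste0("input not found: ", sp$fasta))
    }
  }
  structure(
    list(
      species = species, orthologs = orthologs, out_dir = out_dir,
      seed = as.integer(seed), min_length = min_length,
      drop_internal_stops = drop_internal_stops, fraction = fraction,
      threshold = threshold, alpha = alpha, cor_method = cor_method,
      n_axes = n_axes, linkage = linkage, distance = distance,
      pr2_scope = pr2_scope, digits = digits
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  abort_if(!file.exists(path), paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

write_round_tsv <- function(df, path, digits) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  readr::write_tsv(df, path)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the full codon-usage analysis end to end
#'
#' Orchestrates the whole pipeline for one or more species: filtering, the
#' per-gene index table, index correlations, correspondence analysis with
#' axis correlations, optimal-codon determination, codon-pair preferences and
#' the cross-species pair diff, RSCU clustering and PCA, and (when an
#' ortholog mapping or Ka/Ks table is supplied) NG86 divergence with
#' index correlations by selection stratum. All stage outputs are written
#' under `config$out_dir` as TSV/JSON/Newick, together with the serialized
#' configuration and a machine-readable `summary.json`.
#'
#' @param config A [run_config()].
#' @param kaks Optional precomputed per-pair divergence tibble (e.g. from
#'   [read_kaks_tsv()]); overrides the internal NG86 estimation.
#' @return Invisibly, a list: `indices` (named per species), `optimal`,
#'   `pairs`, `coa`, `correlations`, `divergence` (or `NULL`), `summary`,
#'   `files`.
#' @export
run_full_analysis <- function(config, kaks = NULL) {
  abort_if(!inherits(config, "run_config"), "`config` must come from run_config()")
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  digits <- config$digits

  cfg_ser <- config
  cfg_ser$species <- lapply(cfg_ser$species, function(sp) {
    if (!is.null(sp$cds)) sp$cds <- paste0("<in-memory: ", nrow(sp$cds), " records>")
    sp
  })
  if (is.data.frame(cfg_ser$orthologs)) {
    cfg_ser$orthologs <- paste0("<in-memory: ", nrow(cfg_ser$orthologs), " pairs>")
  }
  jsonlite::write_json(unclass(cfg_ser), out("config.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  files <- c(files, out("config.json"))

  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stage_log(stage, sprintf("done in %.1fs", as.numeric(Sys.time() - t0, "secs")))
    res
  }

  # -- filter + indices per species ------------------------------------------
  species_res <- list()
  for (sp in config$species) {
    label <- sp$label
    cds <- run_stage(paste0("filter:", label), {
      raw <- if (!is.null(sp$cds)) sp$cds else read_cds_fasta(sp$fasta, label)
      if (!is.null(sp$expression)) raw <- read_expression_tsv(sp$expression, raw)
      kept <- filter_cds(raw, min_length = config$min_length,
                         drop_internal_stops = config$drop_internal_stops)
      write_round_tsv(cds_filter_report(kept),
                      out(paste0(label, "_filter_report.tsv")), digits)
      kept
    })
    abort_if(nrow(cds) == 0, paste0("no sequences pass filtering for ", label))

    idx <- run_stage(paste0("indices:", label), {
      tab <- codon_usage_indices(cds, pr2_scope = config$pr2_scope)
      write_round_tsv(tab, out(paste0(label, "_indices.tsv")), digits)
      jsonlite::write_json(
        tibble::as_tibble(attr(tab, "cai_weights")),
        out(paste0(label, "_cai_weights.json")), digits = NA
      )
      tab
    })

    opt <- run_stage(paste0("optimal:", label), {
      rec <- find_optimal_codons(cds, indices = idx, fraction = config$fraction,
                                 threshold = config$threshold, alpha = config$alpha)
      write_round_tsv(tibble::as_tibble(rec),
                      out(paste0(label, "_optimal_codons.tsv")), digits)
      rec
    })

    pairs <- run_stage(paste0("pairs:", label), {
      tab <- count_codon_pairs(cds)
      write_round_tsv(tibble::as_tibble(tab),
                      out(paste0(label, "_codon_pairs.tsv")), digits)
      tab
    })

    corr <- run_stage(paste0("correlations:", label), {
      cm <- suppressWarnings(index_correlation_matrix(idx, method = config$cor_method))
      write_round_tsv(tibble::as_tibble(cm),
                      out(paste0(label, "_index_correlations.tsv")), digits)
      cm
    })

    coa <- run_stage(paste0("coa:", label), {
      res <- suppressWarnings(
        correspondence_analysis(rscu_matrix(codon_count_matrix(cds)),
                                n_axes = config$n_axes)
      )
      write_round_tsv(res$gene_coords, out(paste0(label, "_coa_genes.tsv")), digits)
      write_round_tsv(res$codon_coords, out(paste0(label, "_coa_codons.tsv")), digits)
      jsonlite::write_json(res$inertia, out(paste0(label, "_coa_inertia.json")),
                           digits = NA)
      res
    })
    axis_corr <- suppressWarnings(
      axis_correlations(coa, idx, method = config$cor_method)
    )
    write_round_tsv(tibble::as_tibble(axis_corr),
                    out(paste0(label, "_axis_correlations.tsv")), digits)

    species_res[[label]] <- list(
      cds = cds, indices = idx, optimal = opt, pairs = pairs,
      correlations = corr, coa = coa, axis_correlations = axis_corr
    )
  }

  labels <- names(species_res)

  # -- cross-species comparisons ---------------------------------------------
  pair_diff <- NULL
  newick <- NULL
  pca <- NULL
  if (length(labels) >= 2) {
    pref <- lapply(species_res, function(r) preferred_pairs(r$pairs))
    pair_diff <- run_stage("pair_diff", {
      d <- diff_preferred_pairs(pref[[1]], pref[[2]], rna = TRUE)
      write_round_tsv(d, out("codon_pair_diff.tsv"), digits)
      d
    })
    all_cds <- dplyr::bind_rows(lapply(species_res, `[[`, "cds"))
    sp_mat <- species_rscu_matrix(all_cds)
    hc <- run_stage("cluster", {
      h <- cluster_species(sp_mat, linkage = config$linkage,
                           distance = config$distance)
      write_dendrogram_newick(h, out("species_dendrogram.nwk"))
      h
    })
    newick <- readLines(out("species_dendrogram.nwk"), warn = FALSE)
    pca <- run_stage("pca", {
      p <- suppressWarnings(pca_species(sp_mat))
      write_round_tsv(p$scores, out("species_pca_scores.tsv"), digits)
      p
    })
  }

  # -- divergence -------------------------------------------------------------
  divergence <- NULL
  if (!is.null(kaks) || !is.null(config$orthologs)) {
    divergence <- run_stage("kaks", {
      pairs_tbl <- if (!is.null(kaks)) {
        kaks
      } else {
        orth <- config$orthologs
        if (is.character(orth)) orth <- read_ortholog_tsv(orth)
        kaks_table(species_res[[1]]$cds, species_res[[2]]$cds, orth)
      }
      cls <- classify_selection(pairs_tbl)
      write_round_tsv(cls$pairs, out("divergence.tsv"), digits)
      write_round_tsv(cls$summary, out("divergence_summary.tsv"), digits)
      div_corr <- tryCatch(
        divergence_index_correlation(cls$pairs, species_res[[1]]$indices,
                                     stratum = "purifying",
                                     method = config$cor_method),
        error = function(e) NULL
      )
      if (!is.null(div_corr)) {
        write_round_tsv(tibble::as_tibble(div_corr),
                        out("divergence_index_correlations.tsv"), digits)
      }
      list(pairs = cls$pairs, summary = cls$summary, correlations = div_corr)
    })
  }

  # -- summary ----------------------------------------------------------------
  per_species <- lapply(species_res, function(r) {
    idx <- r$indices
    opt <- optimal_codon_set(r$optimal)
    tally <- attr(opt, "ending_base_tally")
    list(
      n_genes = nrow(idx),
      mean_gc = mean(idx$gc, na.rm = TRUE),
      mean_gc3s = mean(idx$gc3s, na.rm = TRUE),
      mean_enc = mean(idx$enc, na.rm = TRUE),
      mean_enc_expected = mean(idx$enc_expected, na.rm = TRUE),
      n_enc_61 = sum(idx$enc == 61, na.rm = TRUE),
      n_enc_lt35 = sum(idx$enc < 35, na.rm = TRUE),
      n_optimal_codons = nrow(opt),
      optimal_codons = opt$codon,
      optimal_ending_c = unname(tally["C"]),
      optimal_ending_g = unname(tally["G"]),
      coa_axis_fractions = r$coa$inertia$fraction
    )
  })
  summary <- list(
    species = per_species,
    n_pair_diffs = if (!is.null(pair_diff)) nrow(pair_diff) else NULL,
    dendrogram_newick = newick,
    pca_explained = if (!is.null(pca)) pca$explained else NULL,
    divergence = if (!is.null(divergence)) {
      s <- divergence$summary
      stats::setNames(
        lapply(seq_len(nrow(s)), function(i) as.list(s[i, -1])),
        s$selection_class
      )
    } else {
      NULL
    },
    seed = config$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       null = "null", digits = 6)

  invisible(list(
    species = species_res, pair_diff = pair_diff, pca = pca,
    divergence = divergence, summary = summary,
    out_dir = config$out_dir
  ))
}
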