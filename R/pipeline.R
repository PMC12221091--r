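# End-to-end orchestration: simulate -> merge -> normalize/DE -> cluster ->
# enrich -> screen, with one seed, plain TSV/JSON stage outputs so any
# stage can be rerun in isolation, and a machine-readable run report whose
# arithmetic identities are checked.

#' Assemble a run configuration
#'
#' @param out_dir Output directory for all stage outputs.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param simulation A [simulation_config()] (inputs are generated), or
#'   `NULL` to use pre-existing input files under `input_dir`.
#' @param input_dir Directory holding the input tables when `simulation`
#'   is `NULL` (same filenames as written by [simulate_all()]).
#' @param thresholds A [significance_thresholds()].
#' @param screen A [screen_config()].
#' @param k Number of temporal clusters.
#' @param n_restarts K-means restarts.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, simulation = simulation_config(seed = seed),
                       input_dir = NULL,
                       thresholds = significance_thresholds(),
                       screen = screen_config(), k = 4, n_restarts = 25) {
  structure(list(out_dir = out_dir, seed = seed, simulation = simulation,
                 input_dir = input_dir, thresholds = thresholds,
                 screen = screen, k = k, n_restarts = n_restarts),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `out_dir`, `seed`, `k`, `n_restarts`,
#' `simulation` (fields of [simulation_config()]), `thresholds` (fields of
#' [significance_thresholds()]), `screen` (fields of [screen_config()]),
#' `input_dir`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  sim <- if (is.null(y$input_dir))
    do.call(simulation_config, c(y$simulation %||% list(),
                                 if (is.null(y$simulation$seed)) list(seed = seed)))
  run_config(
    out_dir = y$out_dir %||% ".",
    seed = seed,
    simulation = sim,
    input_dir = y$input_dir,
    thresholds = do.call(significance_thresholds, y$thresholds %||% list()),
    screen = do.call(screen_config, y$screen %||% list()),
    k = y$k %||% 4, n_restarts = y$n_restarts %||% 25
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_sp(paste0("stage '", name, "' failed: ", conditionMessage(e)),
             "settleprot_pipeline_error")
  })
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, writes every stage output as
#' TSV/JSON under `config$out_dir`, and returns (and writes) a run report
#' with stage-wise counts and arithmetic-identity checks.
#'
#' @param config A [run_config()].
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)

  in_dir <- if (!is.null(config$simulation)) {
    stage("simulate", simulate_all(config$simulation,
                                   file.path(out_dir, "inputs"))$dir)
  } else config$input_dir
  if (is.null(in_dir) || !dir.exists(in_dir))
    abort_sp("stage 'inputs': input directory missing",
             "settleprot_pipeline_error")
  f <- function(name) {
    p <- file.path(in_dir, name)
    if (!file.exists(p))
      abort_sp(paste0("stage 'inputs': missing input file ", p),
               "settleprot_pipeline_error")
    p
  }

  m <- stage("read", read_intensity_table(f("intensities.tsv"), f("design.tsv")))
  report$n_proteins <- nrow(m$values)
  report$n_samples <- ncol(m$values)

  # proteome merge over the two annotation id spaces
  merge <- stage("merge", {
    ids_a <- readLines(f("ids_a.txt"))
    ids_b <- readLines(f("ids_b.txt"))
    hits_ab <- read_hit_table(f("hits_ab.tsv"))
    hits_ba <- read_hit_table(f("hits_ba.tsv"))
    pairs <- reciprocal_best_hits(hits_ab, hits_ba)
    mm <- build_nonredundant(ids_a, ids_b, pairs, hits_ab, hits_ba)
    write_tsv_sp(mm$entries, file.path(out_dir, "merge_map.tsv"))
    mm
  })
  report$merge <- as.list(merge$log)

  de <- stage("de", {
    g <- glog_normalize(m)
    bc <- batch_correct(g)
    fit <- fit_moderated(bc)
    tab <- adjust_and_call(fit$table, config$thresholds)
    write_tsv_sp(tab, file.path(out_dir, "contrasts.tsv"))
    list(matrix = bc, fit = fit, table = tab, summary = summarize_de(tab))
  })
  report$de <- de$summary$counts
  report$de$d0 <- de$fit$params$d0
  report$de$s0_sq <- de$fit$params$s0_sq
  jsonlite::write_json(de$summary$counts, file.path(out_dir, "de_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  cl <- stage("cluster", {
    pca <- pca_samples(de$matrix)
    sig_ids <- de$summary$per_protein$protein_id[
      nzchar(de$summary$per_protein$up_at) |
        nzchar(de$summary$per_protein$down_at)]
    prof <- center_profiles(de$matrix)[sig_ids, , drop = FALSE]
    model <- kmeans_pearson(prof, k = config$k, seed = config$seed,
                            n_restarts = config$n_restarts,
                            design = de$matrix$design)
    write_tsv_sp(data.frame(protein_id = names(model$assignments),
                            cluster = unname(model$assignments)),
                 file.path(out_dir, "cluster_assignments.tsv"))
    write_tsv_sp(data.frame(cluster = rownames(model$centroid_by_timepoint),
                            model$centroid_by_timepoint, check.names = FALSE),
                 file.path(out_dir, "cluster_centroids.tsv"))
    write_tsv_sp(data.frame(component = seq_along(pca$variance_fraction),
                            variance_fraction = pca$variance_fraction),
                 file.path(out_dir, "pca_variance.tsv"))
    list(pca = pca, model = model)
  })
  report$cluster <- list(
    sizes = as.list(table(cl$model$assignments)),
    n_excluded = nrow(cl$model$excluded),
    inertia = cl$model$inertia,
    pc1_variance_pct = 100 * cl$pca$variance_fraction[1],
    pc2_variance_pct = 100 * cl$pca$variance_fraction[2]
  )

  enr <- stage("enrich", {
    ann <- read_annotation_map(f("annotations_kog.tsv"), "KOG_class")
    background <- rownames(m$values)
    fgs <- split(names(cl$model$assignments), cl$model$assignments)
    up_ids <- names(de$summary$up_at)[
      vapply(de$summary$up_at, length, integer(1)) > 0]
    down_ids <- names(de$summary$down_at)[
      vapply(de$summary$down_at, length, integer(1)) > 0]
    fgs$up <- up_ids
    fgs$down <- down_ids
    rec <- enrich_sets(ann, fgs, background)
    write_tsv_sp(rec, file.path(out_dir, "enrichment.tsv"))
    rec
  })
  report$enrichment <- list(
    n_records = nrow(enr),
    n_over_flagged = sum(enr$over_flag),
    n_under_flagged = sum(enr$under_flag)
  )

  scr <- stage("screen", {
    hits <- read_hit_table(f("screen_hits.tsv"),
                           utils::read.delim(f("taxon_map.tsv"),
                                             stringsAsFactors = FALSE))
    og <- read_orthogroups(f("orthogroups.tsv"),
                           utils::read.delim(f("genome_lineages.tsv"),
                                             stringsAsFactors = FALSE))
    top <- select_top_hits(hits, config$screen$top_n)
    calls <- classify_lineage(top, rownames(m$values), config$screen)
    calls <- bin_deltas(calls)
    flags <- orthogroup_filter(og, de$summary, config$screen)
    cand <- combine_candidates(calls, flags, de$summary, config$screen)
    write_tsv_sp(calls, file.path(out_dir, "lineage_calls.tsv"))
    write_tsv_sp(cand, file.path(out_dir, "candidates.tsv"))
    cand
  })
  report$screen <- list(
    n_candidates = sum(scr$candidate),
    n_blast_path = sum(scr$passed_blast & scr$candidate),
    n_orthogroup_path = sum(scr$passed_orthogroup & scr$candidate),
    group_counts = as.list(table(scr$group))
  )

  report$identities <- list(
    de_accounting = isTRUE(de$summary$counts$accounting_disjoint),
    cluster_sizes_sum = sum(unlist(report$cluster$sizes)) +
      report$cluster$n_excluded == de$summary$counts$n_unique_de,
    merge_accounting = unname(
      merge$log["n_entries"] == merge$log["n_pairs"] +
        merge$log["n_unpaired_a"] + merge$log["n_unpaired_b"]),
    screen_union = all(scr$candidate ==
      ((scr$passed_blast | scr$passed_orthogroup) &
         nzchar(scr$upregulated_at)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
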