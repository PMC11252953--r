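#' Configuration for a full pipeline run
#'
#' Aggregates every stage parameter with the study defaults: LOD multiplier
#' 5, mixed-model batch size 50, top 800 aptamers by absolute fold change,
#' regularization pair (0.1, 0.001), 1000 stability resamples with retention
#' threshold 0.8, 20 Louvain runs, minimum labeled community size 3, and the
#' healthy/mild pair in the joint graphical model.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param synth a [synthetic_config()] to simulate input data, or NULL when
#'   `input_dir` points at an existing CSV triplet.
#' @param input_dir directory with `intensity.csv`, `samples.csv`,
#'   `annotations.csv` (ignored when `synth` is given).
#' @param lod_k buffer-SD multiplier for the LOD.
#' @param batch_size,top_n,lambda1,lambda2,B,pi_thr,subset_fraction,louvain_runs
#'   stage parameters (see the stage functions).
#' @param ggm_groups the two groups modelled jointly.
#' @param ref_group reference group for contrasts.
#' @param seed global seed; per-stage sub-seeds are derived deterministically
#'   as `seed + stage offset` so stages can be re-run in isolation.
#' @param ms an optional `sfggm_ms` table for cross-platform validation;
#'   `TRUE` simulates one from the synthetic data.
#' @return an `sfggm_run_config` list.
#' @export
run_config <- function(out_dir, synth = NULL, input_dir = NULL,
                       lod_k = 5, batch_size = 50, top_n = 800,
                       lambda1 = 0.1, lambda2 = 0.001, B = 1000,
                       pi_thr = 0.8, subset_fraction = 0.8,
                       louvain_runs = 20,
                       ggm_groups = c("healthy", "mild"),
                       ref_group = "healthy", seed = 1L, ms = NULL) {
  if (is.null(synth) && is.null(input_dir))
    stop("either synth or input_dir must be given")
  stopifnot(length(ggm_groups) == 2, abs(seed) < 2^31 - 10)
  structure(list(out_dir = out_dir, synth = synth, input_dir = input_dir,
                 lod_k = lod_k, batch_size = batch_size, top_n = top_n,
                 lambda1 = lambda1, lambda2 = lambda2, B = B,
                 pi_thr = pi_thr, subset_fraction = subset_fraction,
                 louvain_runs = louvain_runs, ggm_groups = ggm_groups,
                 ref_group = ref_group, seed = as.integer(seed), ms = ms),
            class = "sfggm_run_config")
}

#' Run the full differential-network pipeline
#'
#' Executes, in order: data simulation or ingestion, LOD computation and
#' aptamer filtering, log2 transformation, batched mixed-model differential
#' abundance, feature selection, joint graphical-model estimation with
#' stability selection, differential-network characterization (edge
#' partition, centralities, consensus communities) and, when MS data is
#' available, cross-platform validation. Every stage output is written under
#' `out_dir` and recorded, with md5 checksums, in `manifest.json`.
#'
#' @param config an [run_config()] object.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sfggm_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(report, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. simulate / ingest
  truth <- NULL
  data <- stage("input", {
    if (!is.null(config$synth)) {
      truth <- make_precision_matrices(config$synth)
      ds <- sample_dataset(truth, config$synth)
      write_synthetic_dataset(ds, config$out_dir, truth = truth)
      ds
    } else read_dataset_csv(config$input_dir)
  })

  # 2. preprocess
  pre <- stage("preprocess", {
    buf_ids <- data$samples$sample_id[data$samples$sample_type == "buffer"]
    study_ids <- data$samples$sample_id[data$samples$sample_type == "study" &
                                          is.na(data$samples$replicate_of)]
    lods <- if (length(buf_ids) >= 2)
      compute_lod(subset_intensity(data$intensity, samples = buf_ids),
                  k = config$lod_k) else NULL
    study <- subset_intensity(data$intensity, samples = study_ids)
    filt <- filter_aptamers(study, data$annotations, lods)
    m_log2 <- log2_transform(filt$matrix)
    jsonlite::write_json(
      list(removed = as.list(filt$report$removed),
           n_retained = filt$report$n_retained,
           n_retained_proteins = filt$report$n_retained_proteins),
      file.path(config$out_dir, "filter_report.json"), auto_unbox = TRUE)
    list(matrix = m_log2, lods = lods, report = filt$report)
  })

  # 3. differential abundance
  contrasts <- stage("diffabund", {
    ct <- diff_abundance(pre$matrix, data$samples, data$annotations,
                         batch_size = config$batch_size, seed = seed + 1L,
                         ref_group = config$ref_group)
    ct <- flag_differential(ct)
    write.table(ct, file.path(config$out_dir, "contrasts.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    ct
  })

  # 4. feature selection + 5. joint GGM with stability selection
  groups <- config$ggm_groups
  non_ref <- setdiff(groups, config$ref_group)[1]
  sel <- stage("select", {
    select_features(contrasts, n_aptamers = config$top_n,
                    contrast = paste0(non_ref, "-", config$ref_group))
  })
  est <- stage("ggm", {
    X_list <- lapply(setNames(groups, groups), function(g) {
      ids <- data$samples$sample_id[data$samples$group %in% g &
                                      data$samples$sample_type == "study" &
                                      is.na(data$samples$replicate_of)]
      pre$matrix$values[ids, sel, drop = FALSE]
    })
    Xs <- standardize_groups(X_list)
    est <- stability_selection(Xs, lambda1 = config$lambda1,
                               lambda2 = config$lambda2, B = config$B,
                               pi_thr = config$pi_thr,
                               subset_fraction = config$subset_fraction,
                               seed = seed + 2L)
    write_graphs(est, tsv_path = file.path(config$out_dir, "edges.tsv"),
                 graphml_prefix = file.path(config$out_dir, "graph"))
    est
  })

  # 6. network characterization
  net <- stage("network", {
    gs <- graphs_from_estimate(est)
    gs_prot <- collapse_to_proteins(gs, data$annotations)
    dn <- partition_edges(gs_prot[[1]], gs_prot[[2]], names = groups)
    communities <- lapply(dn$unique, louvain_consensus,
                          runs = config$louvain_runs, seed = seed + 3L)
    cent <- lapply(seq_along(groups), function(i)
      centrality_table(dn$unique[[i]], partition = communities[[i]],
                       contrasts = contrasts,
                       contrast = paste0(non_ref, "-", config$ref_group)))
    names(cent) <- groups
    for (g in groups)
      write.table(cent[[g]],
                  file.path(config$out_dir, paste0("centrality_", g, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(dn$counts, file.path(config$out_dir, "edge_partition.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    list(graphs = gs_prot, diff = dn, communities = communities,
         centrality = cent)
  })

  # 7. cross-platform validation (optional)
  xval <- NULL
  ms <- config$ms
  if (isTRUE(ms) && !is.null(config$synth))
    ms <- stage("crossval", simulate_ms_validation(data, seed = seed + 4L))
  if (inherits(ms, "sfggm_ms")) {
    xval <- stage("crossval", {
      network_prot <- unique(unlist(lapply(net$graphs, function(g)
        igraph::V(g)$name)))
      # graphs are gene-labeled; map back to UniProt
      ann <- data$annotations
      network_up <- unique(ann$uniprot_ids[ann$gene_symbol %in% network_prot |
                                             ann$uniprot_ids %in% network_prot])
      network_up <- network_up[nzchar(network_up)]
      filt <- overlap_filter(ms, network_up)
      soma_prot <- aggregate_to_proteins(pre$matrix, ann)
      corr <- cross_correlate(ms, soma_prot)
      fc <- compare_foldchanges(ms, data$samples, contrasts,
                                contrast = paste0(non_ref, "-",
                                                  config$ref_group),
                                ref_group = config$ref_group)
      write.table(fc, file.path(config$out_dir, "crossval_fc.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      list(filter = filt, correlation = corr, foldchanges = fc)
    })
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("sfggm")),
    seed = seed,
    stage_seeds = list(diffabund = seed + 1L, ggm = seed + 2L,
                       network = seed + 3L, crossval = seed + 4L),
    parameters = config[c("lod_k", "batch_size", "top_n", "lambda1",
                          "lambda2", "B", "pi_thr", "subset_fraction",
                          "louvain_runs", "ggm_groups", "ref_group")],
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, truth = truth, preprocess = pre,
                 contrasts = contrasts, selection = sel, estimate = est,
                 network = net, crossval = xval, manifest = manifest))
}
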