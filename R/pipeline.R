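# End-to-end driver: DI selection -> pair filter -> assembly -> path
# scoring -> top-path selection -> merging -> model scoring -> optional
# interface filter -> evaluation, with artifacts written to an output
# directory.

#' Pipeline configuration
#'
#' Collects every tunable of the coalesce pipeline with its standard
#' defaults: the pair-filter cutoffs, the 4.0 Angstrom clustering cutoff,
#' the DI selection depth (4500 per window), the number of paths kept by
#' Path Score (1000), and the trained Path/Model Score weights.
#'
#' @param cutoffs A [pair_cutoffs()].
#' @param cluster A [cluster_params()].
#' @param top_k_di Docked fragments kept per window by lowest DI score.
#' @param keep_paths Paths kept by lowest Path Score.
#' @param path_weights,model_weights [score_weights()] for the two stages.
#' @param interface_z Z-score cutoff of the optional interface pre-filter.
#' @param contact_cutoff Heavy-atom contact distance (Angstrom).
#' @param model_channel_rho Spearman correlation of the synthetic model
#'   score channels with ligand RMSD (used when no external channels are
#'   supplied).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoffs = pair_cutoffs(),
                            cluster = cluster_params(4.0),
                            top_k_di = 4500L,
                            keep_paths = 1000L,
                            path_weights = score_weights(0.5, 0.1, 0.3, 0.1, 0.3),
                            model_weights = score_weights(0.1, 0.2, 0.3, 0.4, 0.3),
                            interface_z = 1.5,
                            contact_cutoff = 5.0,
                            model_channel_rho = 0.7) {
  structure(list(cutoffs = cutoffs, cluster = cluster,
                 top_k_di = as.integer(top_k_di),
                 keep_paths = as.integer(keep_paths),
                 path_weights = path_weights, model_weights = model_weights,
                 interface_z = interface_z, contact_cutoff = contact_cutoff,
                 model_channel_rho = model_channel_rho),
            class = "pipeline_config")
}

#' Run the coalesce pipeline on pose pools
#'
#' Executes the full coalesce phase: per-window DI selection, pairwise
#' compatibility filtering, extend-and-cluster assembly, Path Score ranking,
#' top-path selection, overlap-averaged merging, Model Score re-ranking,
#' optional interface-prediction pre-filtering, and (when the native ligand
#' is available) CAPRI-style evaluation. All artifacts (ranked models as
#' PDB, score tables as TSV, a JSON manifest with stage-wise path counts)
#' are written under `outdir` when given.
#'
#' @param receptor An `idp_structure` (role receptor).
#' @param pools List of per-window [pose_pool()]s with score channels.
#' @param windows Window table from [make_windows()].
#' @param config A [pipeline_config()].
#' @param native_bb Optional native ligand backbone for evaluation.
#' @param model_channels Optional data frame of 4 model score channels (one
#'   row per kept path); synthesised from ligand RMSD when absent and a
#'   native is available, otherwise from the path's own component scores.
#' @param predicted_interface Optional integer vector of predicted receptor
#'   interface residues for the pre-filter.
#' @param outdir Optional output directory.
#' @param seed Seed for the synthetic model channels.
#' @return List with `paths` (scored `path_set`), `kept` (indices of kept
#'   paths), `models` (list of `merged_model`), `model_scores`, `ranking`
#'   (model order), `metrics` and `rank_metrics` (when a native was given),
#'   and `manifest`.
#' @export
run_pipeline <- function(receptor, pools, windows, config = pipeline_config(),
                         native_bb = NULL, model_channels = NULL,
                         predicted_interface = NULL, outdir = NULL,
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "assembly_stage_error")) stop(e)
      stop(errorCondition(sprintf("pipeline stage '%s' failed: %s",
                                  name, conditionMessage(e)),
                          class = c("pipeline_stage_error", "error"),
                          stage = name))
    })
  }
  # 1. DI selection per window
  pools <- stage("di_selection", {
    lapply(pools, function(p) {
      if (is.null(p$channels)) stopf("pool for window %d lacks score channels",
                                     p$window_index)
      di <- di_score(p$channels)
      keep <- select_top(di, min(config$top_k_di, pool_size(p)), p$pose_ids)
      pool_subset(p, keep)
    })
  })
  pose_di <- lapply(pools, function(p) {
    di <- di_score(p$channels)
    names(di) <- p$pose_ids
    di
  })
  # 2. pair filter + 3. assembly
  compat <- stage("pair_filter", filter_pools(pools, config$cutoffs))
  paths <- stage("assembly",
                 assemble(pools, compat, config$cluster, pose_scores = pose_di))
  # 4. path scoring and selection
  paths <- stage("path_scoring",
                 path_component_scores(paths, pose_di, receptor,
                                       config$contact_cutoff))
  s_path <- if (n_paths(paths) >= 2L) {
    path_score(paths, config$path_weights)
  } else {
    0   # a single surviving path needs no relative ranking
  }
  path_ids <- apply(paths$poses, 1, paste, collapse = "|")
  kept <- select_top(s_path, min(config$keep_paths, n_paths(paths)), path_ids)
  # 5. merge into full-length models
  models <- stage("merge", lapply(kept, function(i) {
    merge_path(paths$coords[i, ], windows)
  }))
  # 6. model scoring
  if (is.null(model_channels)) {
    set.seed(seed + 7L)
    truth <- if (!is.null(native_bb)) {
      vapply(models, function(m) ligand_rmsd(m$backbone, native_bb), numeric(1))
    } else {
      # without a native, channels derive from the path's own energy score
      paths$component_scores$S_E[kept]
    }
    model_channels <- generate_channels(truth, config$model_channel_rho,
                                        n_channels = 4L,
                                        names = c("itscorepro", "dfire",
                                                  "molmech", "goap"))
  }
  s_model <- if (length(models) >= 2L) {
    model_score(model_channels, config$model_weights)
  } else {
    rep(0, length(models))
  }
  survivors <- seq_along(models)
  iface <- NULL
  if (!is.null(predicted_interface)) {
    iface <- interface_filter(models, predicted_interface, receptor,
                              config$interface_z, config$contact_cutoff)
    survivors <- iface$keep
  }
  ranking <- survivors[order(s_model[survivors], survivors)]
  # 7. evaluation
  metrics <- NULL; rmetrics <- NULL
  if (!is.null(native_bb)) {
    metrics <- stage("evaluation", lapply(ranking, function(i) {
      eval_model(models[[i]]$backbone, native_bb, receptor,
                 config$contact_cutoff)
    }))
    rmetrics <- suppressWarnings(rank_metrics(metrics))
  }
  manifest <- list(
    n_windows = nrow(windows),
    pool_sizes = vapply(pools, pool_size, integer(1)),
    stage_counts = paths$stage_counts,
    n_paths = n_paths(paths),
    n_kept = length(kept),
    path_weights = unlist(config$path_weights),
    model_weights = unlist(config$model_weights),
    kept_pose_ids = paths$poses[kept, , drop = FALSE],
    ranking = ranking,
    seed = seed
  )
  out <- list(paths = paths, path_scores = s_path, kept = kept,
              models = models, model_scores = s_model, ranking = ranking,
              interface = iface, metrics = metrics, rank_metrics = rmetrics,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(out, receptor, outdir)
  invisible(out)
}

#' @keywords internal
write_pipeline_outputs <- function(out, receptor, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_structure(receptor, file.path(outdir, "receptor.pdb"))
  top <- utils::head(out$ranking, 10L)
  for (r in seq_along(top)) {
    m <- out$models[[top[r]]]
    write_structure(model_as_structure(m),
                    file.path(outdir, sprintf("model_rank%02d.pdb", r)))
  }
  scores <- data.frame(
    model = seq_along(out$models),
    model_score = out$model_scores
  )
  utils::write.table(scores, file.path(outdir, "model_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  path_tab <- cbind(
    as.data.frame(out$paths$poses[out$kept, , drop = FALSE]),
    out$paths$component_scores[out$kept, , drop = FALSE],
    S_path = out$path_scores[out$kept]
  )
  utils::write.table(path_tab, file.path(outdir, "kept_paths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- out$manifest
  manifest$kept_pose_ids <- apply(manifest$kept_pose_ids, 1, paste,
                                  collapse = "|")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
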