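# Pipeline orchestration: the three run modes mirror the method's ablation
# ladder. "picasso_b" is the baseline (one global threshold per scale,
# complexity budget 0); "picasso_l" adds per-branch local thresholds with a
# budget of 0.15; "picasso" is the full method, which additionally prunes
# the tolerated cycles and subtracts the reconstructed artifact volume.

#' Pipeline run configuration
#'
#' @param mode `"picasso"` (full), `"picasso_l"` (local thresholds, no
#'   leakage removal) or `"picasso_b"` (baseline; forces
#'   `max_complexity = 0` and skips refinement).
#' @param search A [threshold_search()]; `max_complexity` is forced to 0
#'   for mode `picasso_b` and defaults to 0.15 otherwise.
#' @param levels Pooling levels `L`.
#' @param sigma,support,orientation_step Tubular bank geometry.
#' @param polarity Appearance polarity, see [appearance_map()].
#' @param preprocess `TRUE` for full lung/vessel/body in-painting, `FALSE`
#'   for none, or `"vessels"` to suppress bright elongated structures only,
#'   treating the whole volume as lung (for phantoms, which have no body
#'   but whose bright airway walls produce the same spurious filter
#'   responses that vessels do in clinical CT).
#' @param root_hint Optional trachea-entry voxel (i, j, k).
#' @param min_component_voxels Distal component size floor.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `picasso_config` list.
#' @export
picasso_config <- function(mode = c("picasso", "picasso_l", "picasso_b"),
                           search = NULL, levels = 3, sigma = c(1, 1, 4),
                           support = 33, orientation_step = pi / 6,
                           polarity = "dark", preprocess = TRUE,
                           root_hint = NULL, min_component_voxels = 2,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(search)) {
    search <- threshold_search(
      max_complexity = if (mode == "picasso_b") 0 else 0.15)
  }
  if (mode == "picasso_b" && search$max_complexity != 0) {
    search <- threshold_search(search$th_min, search$th_max, search$tol, 0)
  }
  structure(list(mode = mode, search = search, levels = levels,
                 sigma = sigma, support = support,
                 orientation_step = orientation_step, polarity = polarity,
                 preprocess = preprocess, root_hint = root_hint,
                 min_component_voxels = min_component_voxels,
                 seed = as.integer(seed)),
            class = "picasso_config")
}

#' Run the full segmentation pipeline
#'
#' Orchestrates pre-processing (optional), the multiresolution initial
#' segmentation with globally optimized thresholds, per-branch distal
#' refinement (modes `picasso_l` / `picasso`), and cycle-pruning leakage
#' removal (mode `picasso` only). Every stage is a pure function of the
#' input volume and the configuration, so repeated runs are identical.
#'
#' @param ct Input [scalar_volume()] (CT in HU) or a path readable by
#'   [read_volume()].
#' @param config A [picasso_config()].
#' @param truth Optional `phantom_truth` for metric reporting.
#' @param output_dir Optional directory; when given, masks, graphs,
#'   metrics and a reproducibility manifest are written there.
#' @return A `picasso_result` list: `segI`, `refined`, `final`, `artifact`,
#'   `levels` (per-level records incl. ThOpt), `branches`, `graph` (final
#'   directed graph), `complexity` (of the final graph), `metrics` (if
#'   truth given) and `config`.
#' @export
run_picasso <- function(ct, config = picasso_config(), truth = NULL,
                        output_dir = NULL) {
  if (is.character(ct)) ct <- read_volume(ct)
  lungs <- NULL
  if (identical(config$preprocess, "vessels")) {
    all_lung <- binary_mask(array(TRUE, dim(ct$data)), ct$spacing, ct$origin)
    vessels <- segment_vessels(ct, all_lung,
                               orientations =
                                 orientation_bank(config$orientation_step))
    ct_in <- inpaint(ct, vessels)
  } else if (isTRUE(config$preprocess)) {
    pre <- preprocess_ct(ct)
    ct_in <- pre$ct
    lungs <- pre$lungs
  } else {
    ct_in <- ct
  }
  bank <- tubular_bank(config$sigma,
                       orientation_bank(config$orientation_step),
                       support = config$support)
  init <- initial_segmentation(ct_in, levels = config$levels,
                               search = config$search, bank = bank,
                               mask = lungs, root_hint = config$root_hint,
                               polarity = config$polarity)
  refined <- init$segI
  branches <- list()
  if (config$mode %in% c("picasso_l", "picasso")) {
    ref <- refine_all(init$segI, init$segUp1, init$E0,
                      search = config$search,
                      min_voxels = config$min_component_voxels)
    refined <- ref$mask
    branches <- ref$branches
  }
  final <- refined
  artifact <- binary_mask(array(FALSE, dim(refined$data)),
                          refined$spacing, refined$origin)
  record <- NULL
  ag <- NULL
  if (config$mode == "picasso") {
    lr <- remove_leakage(refined, multiscale_appearance(init$levels),
                         root_hint = config$root_hint,
                         protect = init$segUp1)
    final <- lr$mask
    artifact <- lr$artifact
    record <- lr$record
    ag <- lr$graph # the pruned graph is the final anatomical graph
  } else {
    sg <- skeletonize(final, E = init$E0, close_gaps = TRUE)
    root <- find_root(final, sg, hint = config$root_hint)
    ag <- direct_graph(sg, root)
  }
  metrics <- if (!is.null(truth)) exact_metrics(final, truth) else NULL
  res <- structure(list(
    segI = init$segI, segUp1 = init$segUp1, refined = refined,
    final = final, artifact = artifact, E0 = init$E0,
    levels = lapply(init$levels, function(r)
      r[c("level", "thopt", "floor_hit")]),
    branches = branches, prune_record = record, graph = ag,
    complexity = complexity(ag), metrics = metrics, config = config),
    class = "picasso_result")
  if (!is.null(output_dir)) write_result_bundle(res, output_dir)
  res
}

#' @export
print.picasso_result <- function(x, ...) {
  cat(sprintf("<picasso_result> mode %s: %d voxels segmented, complexity %.4f\n",
              x$config$mode, sum(x$final$data), x$complexity))
  for (l in x$levels)
    cat(sprintf("  level %d: ThOpt = %.4g%s\n", l$level, l$thopt,
                if (l$floor_hit) " (floor)" else ""))
  if (!is.null(x$metrics))
    cat(sprintf("  branches %d (%.1f%%), TLD %.1f mm (%.1f%%), FPR %.2f%%\n",
                x$metrics$branch_count, x$metrics$branch_pct,
                x$metrics$tree_length_mm, x$metrics$tree_length_pct,
                x$metrics$fpr_pct))
  invisible(x)
}

write_result_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(res$segI, file.path(dir, "segI.nii.gz"))
  write_volume(res$refined, file.path(dir, "refined.nii.gz"))
  write_volume(res$final, file.path(dir, "final.nii.gz"))
  write_volume(res$artifact, file.path(dir, "artifact.nii.gz"))
  write_graph_file(res$graph, file.path(dir, "final_graph.graphml"))
  manifest <- list(
    package = "picasso",
    version = as.character(utils::packageVersion("picasso")),
    mode = res$config$mode,
    seed = res$config$seed,
    search = unclass(res$config$search),
    levels = res$config$levels,
    sigma = res$config$sigma,
    support = res$config$support,
    orientation_step = res$config$orientation_step,
    thopt = lapply(res$levels, function(l) l$thopt),
    complexity = res$complexity,
    metrics = res$metrics)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' Reads the config keys of [picasso_config()] (plus nested
#' `search: {th_min, th_max, tol, max_complexity}`) from a YAML file;
#' explicit arguments override file values.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [picasso_config()].
#' @return A `picasso_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$search)) y$search <- do.call(threshold_search, y$search)
  over <- list(...)
  for (nm in names(over)) y[[nm]] <- over[[nm]]
  do.call(picasso_config, y)
}
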