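#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the pipeline in one serializable object.  A
#' resolved copy is written next to the outputs of every run.
#'
#' @param table,meta Input paths (delimited table + JSON metadata sidecar);
#'   alternatively pass a ready [mixed_dataset()] as `dataset`.
#' @param dataset Optional [mixed_dataset()] (overrides `table`/`meta`).
#' @param delta_column,delta_row Missingness filter thresholds.
#' @param imputer `"svd_complete"` or `"svd_full"`.
#' @param k SVD order for the imputer, or `"auto"` for the PCA
#'   intrinsic-dimension heuristic.
#' @param scaling Apply [optimal_scaling()] after imputation.
#' @param drop_first Drop-one dummy coding for categorical variables.
#' @param n_components PCA reduction dimension, or `"auto"`.
#' @param lambda,mu,alpha,R0 Elastic parameters (see [elastic_params()]).
#' @param n_nodes Number of tree nodes.
#' @param prune,extend Post-process the tree ([prune_tree()],
#'   [extend_leaves()]).
#' @param root Root node id, or a list `list(variable =, target_class =)`
#'   for [select_root()], or `NULL` to use the lowest-index leaf.
#' @param associations Run [screen_associations()].
#' @param survival `NULL`, or a list `list(event =, cause =, covariates =)`
#'   naming an event variable (and optional cause variable / covariate
#'   names) for per-trajectory survival analysis.
#' @param layout Compute the 2-D layout.
#' @param out_dir Output directory (created).
#' @param seed Integer seed governing all randomness of the run.
#' @param ... Further options stored verbatim.
#' @return List of class `run_config`.
#' @export
run_config <- function(table = NULL, meta = NULL, dataset = NULL,
                       delta_column = 0.3, delta_row = 0.2,
                       imputer = "svd_complete", k = "auto",
                       scaling = TRUE, drop_first = FALSE,
                       n_components = "auto",
                       lambda = 0.05, mu = 0.1, alpha = 0.01, R0 = Inf,
                       n_nodes = 50L, prune = TRUE, extend = TRUE,
                       root = NULL, associations = TRUE, survival = NULL,
                       layout = TRUE, out_dir = tempfile("pseudotree_run_"),
                       seed = 1L, ...) {
  cfg <- c(as.list(environment()), list(...))
  if (!cfg$imputer %in% c("svd_complete", "svd_full"))
    stopf("unknown imputer '%s' (use svd_complete or svd_full)", cfg$imputer)
  if (!identical(cfg$k, "auto") && !is_count(cfg$k))
    stopf("k must be 'auto' or a positive integer")
  if (!identical(cfg$n_components, "auto") && !is_count(cfg$n_components))
    stopf("n_components must be 'auto' or a positive integer")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON (or YAML, if the yaml package is
#' installed)
#' @param path Config file path.
#' @param ... Overrides applied on top of the file values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML config requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "NA")
}

#' Run the full trajectory-inference pipeline
#'
#' Executes, in order: missingness filtering, univariate quantification,
#' SVD imputation, optimal scaling, z-scoring, PCA reduction, elastic
#' principal tree learning (with pruning and leaf extension), segment
#' decomposition and partition, root selection, trajectory extraction,
#' pseudo-time, association screening, per-trajectory survival analysis and
#' the 2-D layout.  Every intermediate artifact is written to the run
#' directory together with a plain-text log and the resolved configuration;
#' the run is fully deterministic given `config$seed`.  A failing stage
#' aborts with the stage name; artifacts of completed stages persist.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`dataset`,
#'   `quantified`, `imputation`, `reduced`, `graph`, `report`, `segments`,
#'   `trajectories`, `root`, `pseudotime`, `associations`, `survival`,
#'   `layout`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log_line("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  cfg_out <- config
  cfg_out$dataset <- if (!is.null(config$dataset)) "in-memory" else NULL
  jsonlite::write_json(Filter(Negate(is.null), unclass(cfg_out)),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  log_line("run seed %d", config$seed)

  ds <- stage("read", {
    if (!is.null(config$dataset)) config$dataset
    else read_dataset(config$table, config$meta)
  })
  ds <- stage("filter", {
    out <- filter_missing(ds, config$delta_column, config$delta_row)
    write_dataset(out, file.path(config$out_dir, "filtered.csv"))
    jsonlite::write_json(attr(out, "filter_report"),
                         file.path(config$out_dir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out
  })
  qm <- stage("quantify", quantify_dataset(ds, drop_first = config$drop_first))
  imp <- stage("impute", {
    k <- if (identical(config$k, "auto")) NULL else config$k
    if (config$imputer == "svd_complete") svd_complete_impute(qm, k = k)
    else svd_full_impute(qm, k = k)
  })
  qm <- imp$qm
  if (isTRUE(config$scaling)) {
    qm <- stage("scale", suppressWarnings(optimal_scaling(qm)))
  }
  qm <- stage("zscore", suppressWarnings(zscore(qm)))
  write_table_csv(data.frame(row_id = rownames(qm$values), qm$values,
                             check.names = FALSE),
                  file.path(config$out_dir, "quantified.csv"))
  red <- stage("reduce", {
    nc <- if (identical(config$n_components, "auto"))
      max(2L, estimate_intrinsic_dimension_pca(qm))
    else config$n_components
    reduce_dimension(qm, min(nc, ncol(qm$values)))
  })
  X <- red$scores
  tree <- stage("tree", {
    fit <- grow_tree(X, n_nodes = config$n_nodes,
                     params = elastic_params(config$lambda, config$mu,
                                             config$alpha, config$R0),
                     seed = config$seed)
    G <- fit$graph
    if (isTRUE(config$prune)) G <- suppressWarnings(prune_tree(G))
    if (isTRUE(config$extend)) G <- extend_leaves(G, X)
    write_principal_graph(G, file.path(config$out_dir, "graph.json"),
                          provenance = list(seed = config$seed,
                                            n_nodes = config$n_nodes))
    utils::write.table(G$nodes, file.path(config$out_dir, "nodes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(G$edges, file.path(config$out_dir, "edges.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    list(graph = G, report = fit$report)
  })
  G <- tree$graph
  segments <- stage("segments", decompose_segments(G))
  root_info <- stage("root", {
    r <- config$root
    if (is.list(r)) {
      sel <- select_root(G, X, ds$values[[r$variable]], r$target_class)
      if (!sel$significant)
        stopf("no significantly enriched root; supply a node id")
      list(node = sel$node, how = "class-enrichment")
    } else if (is.numeric(r)) {
      list(node = as.integer(r), how = "user")
    } else {
      list(node = which(graph_degrees(G) <= 1L)[1], how = "first-leaf")
    }
  })
  trajectories <- stage("trajectories",
                        extract_trajectories(G, root_info$node, segments))
  pt <- stage("pseudotime", {
    out <- compute_pseudotime(X, G, root_info$node, segments, trajectories)
    flat <- out
    flat$trajectories <- vapply(out$trajectories, paste, character(1),
                                collapse = ";")
    write_table_csv(flat, file.path(config$out_dir, "pseudotime.csv"))
    out
  })
  assoc <- NULL
  if (isTRUE(config$associations)) {
    assoc <- stage("associate", {
      sc <- screen_associations(ds, pt)
      write_table_csv(sc$trajectory_table,
                      file.path(config$out_dir, "associations_trajectories.csv"))
      write_table_csv(sc$segment_table,
                      file.path(config$out_dir, "associations_segments.csv"))
      sc
    })
  }
  surv <- NULL
  if (!is.null(config$survival)) {
    surv <- stage("survival", {
      sv <- config$survival
      evvar <- ds$values[[sv$event]]
      evlev <- ds$meta[[sv$event]]$levels
      event <- as.integer(evvar == evlev[length(evlev)])
      covs <- if (!is.null(sv$covariates)) qm$values[, sv$covariates,
                                                     drop = FALSE]
      res <- list()
      for (tr in trajectories) {
        et <- tryCatch(
          trajectory_events(pt, tr$id, event,
                            cause = if (!is.null(sv$cause)) ds$values[[sv$cause]],
                            covariates = covs),
          error = function(e) NULL)
        if (is.null(et) || sum(et$event) < 2) next
        na_curve <- nelson_aalen(et)
        write_table_csv(na_curve,
                        file.path(config$out_dir,
                                  sprintf("hazard_trajectory_%d.csv", tr$id)))
        res[[as.character(tr$id)]] <- list(
          events = et, hazard = na_curve,
          cox = if (!is.null(covs) && sum(et$event) > ncol(covs))
            tryCatch(cox_regression(et), error = function(e) NULL))
      }
      res
    })
  }
  lay <- NULL
  if (isTRUE(config$layout)) {
    lay <- stage("layout", {
      gl <- layout_graph(G, seed = config$seed)
      pl <- place_points(X, G, gl, seed = config$seed)
      jsonlite::write_json(
        list(nodes = unname(split(gl$coords, row(gl$coords))),
             points = pl[, c("x", "y")], scattering = attr(pl, "scattering")),
        file.path(config$out_dir, "layout.json"),
        auto_unbox = TRUE, digits = NA)
      list(graph = gl, points = pl)
    })
  }
  log_line("pipeline complete: %s", config$out_dir)
  invisible(list(dataset = ds, quantified = qm, imputation = imp,
                 reduced = red, graph = G, report = tree$report,
                 segments = segments, trajectories = trajectories,
                 root = root_info, pseudotime = pt, associations = assoc,
                 survival = surv, layout = lay, out_dir = config$out_dir))
}
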