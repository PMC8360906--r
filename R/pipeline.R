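#' Pipeline run configuration
#'
#' Merged configuration for the end-to-end pipeline. Defaults reproduce the
#' reference setting: mechanical parameters `(lambda, gamma) =
#' (0.259, 0.172)`, a 400-cell tissue with a 19-cell central cluster, and a
#' contractility grid from 0 to 20 percent in 1-percent steps.
#'
#' @param ... overrides of the default fields (see Details).
#' @details Fields: `lambda`, `gamma`, `n_cells`, `cluster_size`, `grid`
#'   (increment grid), `seeds` (simulation seeds for the sweep),
#'   `true_increment` (used when the experimental dataset is generated
#'   synthetically), `n_pseudo_embryos`, `vertex_jitter_sigma`,
#'   `experiment_csv` (path to an experimental angle table; `NULL` =
#'   generate synthetically), `relax_tol`, `peff_tol`, `master_seed`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    lambda = 0.259,
    gamma = 0.172,
    n_cells = 400,
    cluster_size = 19,
    grid = seq(0, 0.20, by = 0.01),
    seeds = 1:5,
    true_increment = 0.09,
    n_pseudo_embryos = 5,
    vertex_jitter_sigma = 0.02,
    experiment_csv = NULL,
    relax_tol = 1e-6,
    peff_tol = 1e-4,
    master_seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] fields.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

# stable hash of the configuration for provenance
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation, measurement and inference: builds a relaxed
#' zero-net-stress tissue, applies the cluster, writes a mesh snapshot
#' (JSON) and per-cell metrics (CSV); obtains the experimental orientation
#' dataset (from `config$experiment_csv`, or generated synthetically at
#' `config$true_increment`); runs the contractility sweep and writes its
#' table (CSV) and summary (JSON); and writes a log plus a MANIFEST of
#' completed stages. Re-running with the same configuration reproduces all
#' numeric outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print progress.
#' @return list with `sweep` (the [contractility_sweep()] result), `metrics`
#'   (per-cell table of the snapshot tissue) and `paths` of all artifacts.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST")
  logf <- file.path(out_dir, "run.log")
  hash <- config_hash(config)
  done <- character(0)
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                            append = TRUE)
  stage_done <- function(s) {
    done <<- c(done, s)
    writeLines(done, manifest)
  }
  cat(sprintf("config hash: %s\npackage: epimech %s\nstarted: %s\n",
              hash, as.character(utils::packageVersion("epimech")),
              format(Sys.time())), file = logf)
  note("defaults in use: n_cells=%d cluster_size=%d relax_tol=%g peff_tol=%g",
       config$n_cells, config$cluster_size, config$relax_tol,
       config$peff_tol)
  note("mechanical parameters: lambda=%g gamma=%g", config$lambda,
       config$gamma)

  # stage 1: snapshot tissue at the configured increment
  par1 <- mechanical_params(config$lambda, config$gamma,
                            cluster_increment = config$true_increment)
  base <- lapply(config$seeds, function(s) base_tissue(config, s))
  stage_done("base_tissues")
  snap <- apply_cluster(base[[1]], par1, target_size = config$cluster_size,
                        tol = config$relax_tol)
  mesh_path <- file.path(out_dir, "mesh_snapshot.json")
  write_tissue_json(snap, mesh_path)
  stage_done("mesh_snapshot")

  metrics <- measure_tissue(snap, par1)
  metrics_path <- file.path(out_dir, "metrics.csv")
  write.csv(metrics, metrics_path, row.names = FALSE)
  note("snapshot metrics: %d cells, %d with undefined axis", nrow(metrics),
       attr(metrics, "n_axis_undefined"))
  stage_done("metrics")

  # stage 2: experimental orientation dataset
  if (!is.null(config$experiment_csv)) {
    ang <- read.csv(config$experiment_csv, stringsAsFactors = FALSE)
    rep_ang <- validate_inputs(config$experiment_csv, "angles")
    if (rep_ang$n_errors > 0)
      stop("invalid experimental angle table; see validate_inputs()")
    by_cat <- split(ang$angle_deg, ang$ring_category)
    for (cat in ORIENTATION_CATEGORIES)
      if (is.null(by_cat[[cat]])) by_cat[[cat]] <- numeric(0)
    exp_ds <- orientation_dataset(by_cat, "experiment")
    note("experimental angles read from %s", config$experiment_csv)
  } else {
    scfg <- synthetic_config(true_increment = config$true_increment,
                             n_pseudo_embryos = config$n_pseudo_embryos,
                             vertex_jitter_sigma = config$vertex_jitter_sigma,
                             n_cells = config$n_cells,
                             cluster_size = config$cluster_size,
                             lambda = config$lambda, gamma = config$gamma,
                             master_seed = config$master_seed)
    trac <- synth_tracings(scfg, verbose = verbose)
    exp_metrics <- measure_tracings(trac, box = attr(trac, "box"))
    exp_ds <- pool_orientations(exp_metrics, "experiment",
                                metadata = list(true_increment =
                                                  config$true_increment))
    note("synthetic pseudo-experiment at true increment %g (%d embryos)",
         config$true_increment, config$n_pseudo_embryos)
  }
  angles_path <- file.path(out_dir, "experiment_angles.csv")
  exp_tab <- do.call(rbind, lapply(ORIENTATION_CATEGORIES, function(cat)
    if (length(exp_ds$angles_by_category[[cat]]))
      data.frame(ring_category = cat,
                 angle_deg = exp_ds$angles_by_category[[cat]])
    else NULL))
  write.csv(exp_tab, angles_path, row.names = FALSE)
  stage_done("experiment_angles")

  # stage 3: contractility sweep
  sweep <- contractility_sweep(exp_ds, config, grid = config$grid,
                               seeds = config$seeds, base_tissues = base,
                               verbose = verbose)
  sweep_path <- file.path(out_dir, "sweep.csv")
  write.csv(sweep$table, sweep_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "sweep_summary.json")
  jsonlite::write_json(
    list(best_increment = sweep$best_increment,
         best_increment_percent = 100 * sweep$best_increment,
         min_summed_distance =
           min(sweep$table$d_total[sweep$table$valid]),
         n_seeds = length(config$seeds),
         config_hash = hash),
    summary_path, auto_unbox = TRUE, digits = NA)
  note("best increment: %g", sweep$best_increment)
  note("finished: %s", format(Sys.time()))
  stage_done("sweep")

  list(sweep = sweep, metrics = metrics,
       paths = list(mesh = mesh_path, metrics = metrics_path,
                    angles = angles_path, sweep = sweep_path,
                    summary = summary_path, log = logf,
                    manifest = manifest))
}

#' Validate an input table
#'
#' Schema and range checks for the CSV dialects consumed by the pipeline:
#' `"tracings"` (polygon simplicity, >= 3 vertices per cell),
#' `"angles"` (angles within [0, 90], known categories),
#' `"recoil"` (strictly increasing times per trace, >= 5 post-ablation
#' points, a pre-ablation baseline), `"divisions"` (finite axes, times
#' within range).
#'
#' @param path CSV file path.
#' @param kind one of `"tracings"`, `"angles"`, `"recoil"`, `"divisions"`.
#' @return object of class `validation_report`: list with `n_errors`,
#'   `errors` (data.frame `row`, `message`) and `kind`; printed
#'   human-readably.
#' @export
validate_inputs <- function(path, kind = c("tracings", "angles", "recoil",
                                           "divisions")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  errs <- list()
  add <- function(row, msg) errs[[length(errs) + 1L]] <<-
    data.frame(row = row, message = msg)
  need <- switch(kind,
    tracings = c("embryo_id", "cell_id", "vertex_order", "x", "y",
                 "is_cluster"),
    angles = c("ring_category", "angle_deg"),
    recoil = c("trace_id", "group", "time_s", "distance"),
    divisions = c("event_id", "time_min", "centroid_x", "centroid_y",
                  "axis_x", "axis_y", "in_plane"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    add(0L, paste("missing column(s):", paste(miss, collapse = ", ")))
  } else if (kind == "angles") {
    bad <- which(!is.finite(df$angle_deg) | df$angle_deg < 0 |
                   df$angle_deg > 90)
    for (b in bad) add(b, sprintf("angle %g outside [0, 90]",
                                  df$angle_deg[b]))
    bad <- which(!df$ring_category %in% ORIENTATION_CATEGORIES)
    for (b in bad) add(b, sprintf("unknown ring category '%s'",
                                  df$ring_category[b]))
  } else if (kind == "tracings") {
    for (emb in unique(df$embryo_id)) {
      te <- df[df$embryo_id == emb, ]
      for (cid in unique(te$cell_id)) {
        pp <- te[te$cell_id == cid, ]
        pp <- pp[order(pp$vertex_order), ]
        row1 <- as.integer(rownames(pp)[1])
        if (nrow(pp) < 3L) {
          add(row1, sprintf("embryo %s cell %s: fewer than 3 vertices",
                            emb, cid))
        } else if (!polygon_is_simple(as.matrix(pp[, c("x", "y")]))) {
          add(row1, sprintf("embryo %s cell %s: self-intersecting polygon",
                            emb, cid))
        }
      }
    }
  } else if (kind == "recoil") {
    for (id in unique(df$trace_id)) {
      tr <- df[df$trace_id == id, ]
      row1 <- as.integer(rownames(tr)[1])
      if (any(diff(tr$time_s) <= 0))
        add(row1 + which(diff(tr$time_s) <= 0)[1],
            sprintf("trace %s: non-increasing timestamps", id))
      if (sum(tr$time_s >= 0) < 5L)
        add(row1, sprintf("trace %s: fewer than 5 post-ablation points", id))
      if (!any(tr$time_s <= 0))
        add(row1, sprintf("trace %s: no pre-ablation baseline point", id))
    }
  } else if (kind == "divisions") {
    bad <- which(!is.finite(df$axis_x) | !is.finite(df$axis_y) |
                   (df$axis_x == 0 & df$axis_y == 0))
    for (b in bad) add(b, "degenerate division axis")
    bad <- which(df$time_min < 0)
    for (b in bad) add(b, sprintf("negative time %g", df$time_min[b]))
  }
  errors <- if (length(errs)) do.call(rbind, errs)
  else data.frame(row = integer(0), message = character(0))
  structure(list(kind = kind, path = path, n_errors = nrow(errors),
                 errors = errors),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation of %s (%s): %d errors\n", x$path, x$kind,
              x$n_errors))
  if (x$n_errors > 0) {
    for (i in seq_len(min(x$n_errors, 20L)))
      cat(sprintf("  row %d: %s\n", x$errors$row[i], x$errors$message[i]))
    if (x$n_errors > 20L) cat(sprintf("  ... and %d more\n", x$n_errors - 20L))
  }
  invisible(x)
}
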