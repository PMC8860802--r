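#' Configuration for a full multipoint analysis run
#'
#' Exactly one of `synthetic` (a [synthetic_spec()]) or the real-input
#' paths (`mesh_path` + `fields_path` + `waveform_path`, with labels either
#' embedded in the mesh file or in `labels_path`) must be given.
#'
#' @param synthetic a [synthetic_spec()], or `NULL` for real inputs.
#' @param mesh_path,fields_path,labels_path,waveform_path input files for
#'   a real run: surface mesh (PLY/STL/VTK), field-series directory
#'   (plain-text layout or VTK sequence), optional region-label sidecar
#'   CSV, and inlet waveform CSV (`time,flow`).
#' @param inlet list with `origin`, `normal`, `thickness` defining the
#'   inlet plane; taken from the generator's ground truth for synthetic
#'   runs when `NULL`.
#' @param period_T cycle period in s (synthetic runs take the spec's).
#' @param cycle_index cardiac cycle whose peak systole is analysed
#'   (default 2).
#' @param spacing multipoint spacing in mm (default 0.5).
#' @param seed RNG seed for the point distribution (and synthetic fields).
#' @param min_divergence_percentile,min_separation_mm,outflow_fraction_threshold
#'   divergence-center detection parameters, see
#'   [find_divergence_centers()].
#' @param contingency_mode passed to [build_center_contingency()].
#' @param weighted_inlet area-weight the inlet averages (default TRUE).
#' @param out_dir optional output directory for run artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, mesh_path = NULL,
                       fields_path = NULL, labels_path = NULL,
                       waveform_path = NULL, inlet = NULL,
                       period_T = NULL, cycle_index = 2L, spacing = 0.5,
                       seed = 1L, min_divergence_percentile = 95,
                       min_separation_mm = 1.0,
                       outflow_fraction_threshold = 0.8,
                       contingency_mode = "as_printed",
                       weighted_inlet = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  has_real <- !is.null(mesh_path)
  if (is.null(synthetic) == !has_real) {
    stop("config error: exactly one of a synthetic spec or real input ",
         "paths must be set")
  }
  if (has_real && (is.null(fields_path) || is.null(waveform_path) ||
                     is.null(inlet) || is.null(period_T))) {
    stop("config error: real runs need mesh_path, fields_path, ",
         "waveform_path, inlet and period_T")
  }
  class(cfg) <- "run_config"
  cfg
}

load_any_field_series <- function(path, mesh) {
  if (file.exists(file.path(path, "meta.json"))) {
    load_field_series(path, mesh)
  } else if (file.exists(file.path(path, "index.json"))) {
    load_vtk_series(path, mesh)
  } else {
    stop("fields stage: no meta.json or index.json under ", path,
         " (hint: use write_field_series() or write_vtk_series() layouts)")
  }
}

#' Run the full multipoint analysis
#'
#' Orchestrates load/generate -> peak-systole selection -> index fields ->
#' point distribution and measurement -> divergence-center detection ->
#' region statistics. With `out_dir` set, writes `points.csv`,
#' `centers.csv`, `summary.csv`/`report.json` and `run_log.txt`; outputs
#' are identical for identical configs.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `report` (a
#'   [summarize_comparison()] result), `points`, `centers`,
#'   `inlet_reference`, `mesh` and the `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    gen <- stage("generate", make_dome_mesh(spec))
    mesh <- gen$mesh
    fs <- stage("generate", make_fields(mesh, gen$truth, seed = config$seed))
    waveform <- synthetic_waveform(spec)
    inlet_def <- gen$truth$inlet
    period_T <- spec$period_T_s
  } else {
    mesh <- stage("mesh", load_mesh(config$mesh_path))
    if (!is.null(config$labels_path)) {
      mesh <- stage("labels", read_region_labels(mesh, config$labels_path))
    }
    if (is.null(mesh$region)) {
      stop("labels stage: mesh carries no region labels ",
           "(hint: supply labels_path)")
    }
    fs <- stage("fields", load_any_field_series(config$fields_path, mesh))
    waveform <- stage("waveform",
                      utils::read.csv(config$waveform_path))
    inlet_def <- config$inlet
    period_T <- config$period_T
  }
  snapshot <- stage("snapshot",
                    select_peak_systole(waveform, config$cycle_index,
                                        period_T))
  inlet <- stage("inlet",
                 define_inlet_plane(mesh, inlet_def$origin,
                                    inlet_def$normal, inlet_def$thickness))
  idx <- stage("indices",
               compute_index_fields(mesh, fs, inlet, snapshot,
                                    weighted = config$weighted_inlet))
  points <- stage("sampling", {
    p <- distribute_points(mesh, domain_label = c("bleb", "nonbleb"),
                           spacing = config$spacing, seed = config$seed)
    p <- label_points(p, mesh)
    p$records <- data.frame(
      normalized_pressure = measure_at_points(p, mesh,
                                              idx$normalized_pressure),
      normalized_wss = measure_at_points(p, mesh, idx$normalized_wss),
      tawss = measure_at_points(p, mesh, idx$tawss),
      osi = measure_at_points(p, mesh, idx$osi))
    p
  })
  centers <- stage("topology", {
    k <- snapshot_step(fs, snapshot)
    tang <- tangential_projection(mesh, fs$wss[, , k])
    div <- surface_divergence(mesh, tang)
    find_divergence_centers(
      mesh, tang, div, domain_label = c("bleb", "nonbleb"),
      min_divergence_percentile = config$min_divergence_percentile,
      min_separation_mm = config$min_separation_mm,
      outflow_fraction_threshold = config$outflow_fraction_threshold)
  })
  points <- stage("topology", flag_center_points(points, centers))
  report <- stage("stats",
                  summarize_comparison(
                    points, contingency_mode = config$contingency_mode))
  result <- structure(
    list(report = report, points = points, centers = centers,
         inlet_reference = idx$inlet_reference, mesh = mesh,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  invisible(result)
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$points),
                   file.path(dir, "points.csv"), row.names = FALSE)
  utils::write.csv(result$centers, file.path(dir, "centers.csv"),
                   row.names = FALSE)
  write_report(result$report, dir)
  cfg <- result$config
  log_lines <- c(
    "blebpoint multipoint analysis run",
    sprintf("seed: %d", cfg$seed),
    sprintf("spacing_mm: %g", cfg$spacing),
    sprintf("cycle_index: %d", cfg$cycle_index),
    sprintf("snapshot_time_s: %g", result$inlet_reference$snapshot_time),
    sprintf("pressure_ave_inlet_pa: %.6f",
            result$inlet_reference$pressure_ave_inlet),
    sprintf("wss_ave_inlet_pa: %.6f", result$inlet_reference$wss_ave_inlet),
    sprintf("min_divergence_percentile: %g", cfg$min_divergence_percentile),
    sprintf("min_separation_mm: %g", cfg$min_separation_mm),
    sprintf("outflow_fraction_threshold: %g",
            cfg$outflow_fraction_threshold),
    sprintf("contingency_mode: %s", cfg$contingency_mode),
    sprintf("weighted_inlet: %s", cfg$weighted_inlet),
    sprintf("input: %s",
            if (is.null(cfg$synthetic)) cfg$mesh_path else "synthetic"),
    sprintf("n_points: %d", nrow(result$points$points)),
    sprintf("n_centers: %d", nrow(result$centers)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Re-analyse printed contingency counts (stats-only mode)
#'
#' Runs the Fisher exact test on a divergence-center counts table (CSV
#' with columns `case,region,centers,points`), per case and pooled, using
#' the as-printed construction (columns = centers, total points), and
#' optionally Mann-Whitney comparisons on a per-point value table (CSV
#' with columns `case,region` plus parameter columns).
#'
#' @param counts_path counts CSV path.
#' @param values_path optional per-point values CSV path.
#' @param contingency_mode passed to [build_center_contingency()].
#' @return list of class `stats_only_report` with `fisher` (data.frame:
#'   one row per case plus `total`) and optionally `mann_whitney`.
#' @export
run_stats_only <- function(counts_path, values_path = NULL,
                           contingency_mode = "as_printed") {
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  need <- c("case", "region", "centers", "points")
  if (!all(need %in% names(counts))) {
    stop("parse error: counts fixture needs columns ",
         paste(need, collapse = ","))
  }
  cases <- unique(counts$case)
  scopes <- c(as.list(cases), list(cases))
  names(scopes) <- c(cases, "total")
  rows <- lapply(names(scopes), function(nm) {
    cs <- counts[counts$case %in% scopes[[nm]], , drop = FALSE]
    agg <- stats::aggregate(cbind(centers, points) ~ region, cs, sum)
    get <- function(reg, col) {
      val <- agg[agg$region == reg, col]
      if (length(val) == 0L) 0L else val
    }
    tab <- rbind(bleb = c(get("bleb", "centers"), get("bleb", "points")),
                 nonbleb = c(get("nonbleb", "centers"),
                             get("nonbleb", "points")))
    if (contingency_mode == "conventional") tab[, 2] <- tab[, 2] - tab[, 1]
    data.frame(case = nm,
               centers_bleb = tab["bleb", 1], n_bleb = get("bleb", "points"),
               centers_nonbleb = tab["nonbleb", 1],
               n_nonbleb = get("nonbleb", "points"),
               prevalence_bleb_pct =
                 100 * tab["bleb", 1] / max(get("bleb", "points"), 1L),
               p_value = fisher_exact_2x2(tab),
               stringsAsFactors = FALSE)
  })
  fisher <- do.call(rbind, rows)
  rownames(fisher) <- NULL
  out <- list(fisher = fisher)
  if (!is.null(values_path)) {
    vals <- utils::read.csv(values_path, stringsAsFactors = FALSE)
    params <- setdiff(names(vals), c("case", "region"))
    if (nrow(vals) > 0L && length(params) > 0L) {
      if (!"case" %in% names(vals)) vals$case <- "case1"
      vals$is_center <- FALSE
      rep2 <- summarize_comparison(vals, parameters = params)
      out$mann_whitney <- rep2$summary
    }
  }
  class(out) <- "stats_only_report"
  out
}

#' Write the bundled fixtures for a stand-alone analysis
#'
#' Materialises the default synthetic case (mesh as labelled PLY, field
#' series in the plain-text layout, waveform CSV, region-label sidecar)
#' plus the published divergence-center contingency counts as
#' `table1_counts.csv`.
#'
#' @param out_dir output directory.
#' @param spec a [synthetic_spec()] (default conditions when missing).
#' @return `out_dir`, invisibly.
#' @export
make_fixtures <- function(out_dir, spec = synthetic_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_dome_mesh(spec)
  fs <- make_fields(gen$mesh, gen$truth)
  write_mesh(gen$mesh, file.path(out_dir, "mesh.ply"))
  write_field_series(fs, file.path(out_dir, "fields"))
  utils::write.csv(synthetic_waveform(spec),
                   file.path(out_dir, "waveform.csv"), row.names = FALSE)
  write_region_labels(gen$mesh, file.path(out_dir, "labels.csv"))
  src <- system.file("extdata", "table1_counts.csv", package = "blebpoint")
  file.copy(src, file.path(out_dir, "table1_counts.csv"), overwrite = TRUE)
  invisible(out_dir)
}
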