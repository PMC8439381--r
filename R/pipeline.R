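#' Run the full analysis battery from a config
#'
#' Config-driven orchestration of the analysis stages in dependency order:
#' fit -> descriptors / hydrogen bonds / secondary structure / essential
#' dynamics -> free-energy landscape and minima -> pocket volume ->
#' energetics -> alanine scan. Every requested stage writes a TSV table
#' into `output_dir`, and a JSON manifest records the package version, the
#' full config (including defaults actually used), the seed, and an md5
#' checksum for every emitted file. All referenced selections are resolved
#' before any analysis runs (fail-fast).
#'
#' The config is a named list (or a YAML file path with the same
#' structure). Recognised top-level fields: `system` (label), `input`
#' (either `structure`/`trajectory`/`parameters` paths or `generator` =
#' list(name, args) naming a generator exported by this package),
#' `frame_window` (c(first, last)), `stride`, `selections` (named list of
#' expressions validated up front), `descriptors` (logical flags `rmsd`,
#' `rmsf`, `rg`, `sasa`; lists `distances`, `angles`, `torsions`,
#' `triangles`, `contact_shells`), `hbonds`, `salt_bridges`,
#' `secondary_structure`, `pca` (with `fel_bins`, `temperature`),
#' `pocket` (inclusion/exclusion sphere specs), `energetics`
#' (complex/receptor/ligand selections), `alanine_scan` (residues),
#' `seed`, `output_dir`.
#'
#' @param config named list or path to a YAML file.
#' @return list of class `pipeline_report`: `system`, `metrics`
#'   (data.frame metric/mean/sd), `outputs` (paths), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$system <- cfg$system %||% "system"
  cfg$seed <- cfg$seed %||% 1L
  cfg$stride <- cfg$stride %||% 1L
  out_dir <- cfg$output_dir %||% stop("config needs output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs ----
  inp <- cfg$input %||% stop("config needs input")
  if (!is.null(inp$generator)) {
    gen <- get(inp$generator$name, envir = asNamespace("mdensemble"))
    obj <- do.call(gen, inp$generator$args %||% list())
    top <- obj$topology; ens <- obj$ensemble
    gen_obj <- obj
  } else {
    st <- read_structure(inp$structure)
    top <- st$topology
    ens <- if (!is.null(inp$trajectory)) {
      read_trajectory(top, inp$trajectory,
                      format = inp$format %||% "dcd", stride = cfg$stride)
    } else st$ensemble
    if (!is.null(inp$parameters)) top <- read_parameters(top, inp$parameters)
    gen_obj <- NULL
  }
  if (!is.null(cfg$frame_window)) {
    fw <- cfg$frame_window
    ens <- subset_frames(ens, seq(max(1L, fw[[1]]),
                                  min(n_frames(ens), fw[[2]])))
  }

  # ---- fail-fast selection validation ----
  sels <- cfg$selections %||% list()
  resolved <- lapply(sels, function(e) select_atoms(top, e))

  outputs <- character(0)
  metrics <- list()
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }
  add_metric <- function(name, mean, sd = NA_real_) {
    metrics[[length(metrics) + 1L]] <<- data.frame(metric = name, mean = mean,
                                                   sd = sd)
  }
  getsel <- function(key, default) {
    if (!is.null(resolved[[key]])) resolved[[key]]
    else default
  }

  dsc <- cfg$descriptors %||% list()
  if (isTRUE(dsc$rg)) {
    ts <- radius_of_gyration(ens, top, getsel("rg", "all"),
                             mass_weighted = TRUE)
    emit("rg.tsv", function(p) write_time_series(ts, p))
    add_metric("Rg_A", ts$summary["mean"], ts$summary["sd"])
  }
  if (isTRUE(dsc$rmsd)) {
    ts <- rmsd_series(ens, top, reference = 1L,
                      fit_sel = getsel("fit", "backbone"))
    emit("rmsd.tsv", function(p) write_time_series(ts, p))
    add_metric("RMSD_A", ts$summary["mean"], ts$summary["sd"])
  }
  if (isTRUE(dsc$rmsf)) {
    rf <- rmsf(ens, top, getsel("rmsf", "calpha"))
    emit("rmsf.tsv", function(p) utils::write.table(rf, p, sep = "\t",
                                                    quote = FALSE,
                                                    row.names = FALSE))
    add_metric("RMSF_mean_A", mean(rf$rmsf), stats::sd(rf$rmsf))
  }
  if (isTRUE(dsc$sasa)) {
    ts <- sasa_series(ens, top, getsel("sasa", "all"),
                      n_sphere_points = dsc$sasa_points %||% 240L)
    emit("sasa.tsv", function(p) write_time_series(ts, p))
    add_metric("SASA_A2", ts$summary["mean"], ts$summary["sd"])
  }
  for (d in dsc$distances %||% list()) {
    ts <- distance_series(ens, top, d$a, d$b)
    emit(sprintf("distance_%s.tsv", d$label %||% "pair"),
         function(p) write_time_series(ts, p))
    add_metric(sprintf("distance_%s_A", d$label %||% "pair"),
               ts$summary["mean"], ts$summary["sd"])
  }
  for (d in dsc$angles %||% list()) {
    ts <- angle_series(ens, top, d$a, d$b, d$c)
    emit(sprintf("angle_%s.tsv", d$label %||% "triple"),
         function(p) write_time_series(ts, p))
    add_metric(sprintf("angle_%s_deg", d$label %||% "triple"),
               ts$summary["mean"], ts$summary["sd"])
  }
  for (d in dsc$triangles %||% list()) {
    ts <- triangle_area_series(ens, top, d$a, d$b, d$c)
    emit(sprintf("triangle_%s.tsv", d$label %||% "abc"),
         function(p) write_time_series(ts, p))
    add_metric(sprintf("triangle_%s_A2", d$label %||% "abc"),
               ts$summary["mean"], ts$summary["sd"])
  }
  for (d in dsc$contact_shells %||% list()) {
    ct <- contact_shell(frame_coords(ens, 1), top, d$center,
                        shell_radius = d$radius %||% 4.0,
                        classify = d$classify %||% FALSE)
    emit(sprintf("contacts_%s.tsv", d$label %||% "shell"),
         function(p) utils::write.table(ct, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    add_metric(sprintf("contacts_%s_n", d$label %||% "shell"), nrow(ct))
  }

  hb <- cfg$hbonds
  if (!is.null(hb)) {
    ot <- hbond_occupancy(ens, top, hb$donor %||% "all",
                          hb$acceptor %||% "all",
                          dist_cutoff = hb$dist_cutoff %||% 3.5,
                          angle_cutoff = hb$angle_cutoff %||% 120,
                          report_cutoff = hb$report_cutoff %||% 0)
    emit("hbond_occupancy.tsv", function(p) write_occupancy_table(ot, p))
    add_metric("hbond_pairs_n", nrow(ot))
    if (nrow(ot)) add_metric("hbond_top_occupancy_pct", max(ot$occupancy))
  }
  if (!is.null(cfg$salt_bridges)) {
    ot <- salt_bridges(ens, top, cutoff = cfg$salt_bridges$cutoff %||% 4.0)
    emit("salt_bridges.tsv", function(p) write_occupancy_table(ot, p))
    add_metric("salt_bridge_pairs_n", nrow(ot))
  }
  if (!is.null(cfg$secondary_structure)) {
    ssm <- ss_timeline(ens, top, cfg$secondary_structure$chain)
    emit("ss_timeline.txt", function(p) write_ss_timeline(ssm, p))
    emit("ss_fractions.tsv",
         function(p) utils::write.table(ssm$fractions, p, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    add_metric("helix_fraction_pct",
               mean(ssm$fractions$H, na.rm = TRUE))
  }

  pca_cfg <- cfg$pca
  if (!is.null(pca_cfg)) {
    sel <- pca_cfg$sel %||% "backbone"
    ft <- fit_to_mean(ens, top, sel)
    C <- covariance_matrix(ft$ensemble, top, sel)
    model <- principal_components(C)
    p1 <- project_mode(ft$ensemble, model, 1L)
    p2 <- project_mode(ft$ensemble, model, 2L)
    grid <- free_energy_landscape(p1, p2, n_bins = pca_cfg$fel_bins %||% 50L,
                                  temperature = pca_cfg$temperature %||% 300)
    mins <- locate_minima(grid, p1, p2)
    emit("fel.tsv", function(p) write_fel_grid(grid, p))
    emit("fel_minima.tsv",
         function(p) utils::write.table(mins, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    emit("pc1_mode.nmd",
         function(p) export_porcupine(model, top, 1L, p))
    dm <- dccm_matrix(ft$ensemble, top, pca_cfg$dccm_sel %||% "calpha")
    emit("dccm.tsv",
         function(p) utils::write.table(round(dm, 6), p, sep = "\t",
                                        quote = FALSE))
    add_metric("pc1_variance_frac", model$frac[1])
    add_metric("fel_minima_n", nrow(mins))
  }

  if (!is.null(cfg$pocket)) {
    pc <- cfg$pocket
    region <- build_region(pc$inclusion, pc$exclusion %||% list(),
                           spacing = pc$spacing %||% 1.0,
                           padding = pc$padding %||% 1.09,
                           contiguity = pc$contiguity %||% 0L)
    vs <- pocket_volume_series(ens, top, region,
                               occluder_sel = pc$occluder %||%
                                 "protein and heavy")
    emit("pocket_volume.tsv", function(p) write_volume_series(vs, p))
    add_metric("pocket_volume_A3", mean(vs$volume), stats::sd(vs$volume))
  }

  en <- cfg$energetics
  if (!is.null(en)) {
    br <- binding_free_energy(ens, top, en$complex, en$receptor, en$ligand,
                              n_sphere_points = en$sasa_points %||% 240L)
    emit("binding_energy.tsv", function(p) write_binding_result(br, p))
    g <- br$summary[br$summary$component == "G_total", ]
    add_metric("dG_bind_kcal", g$mean, g$sd)
    rl <- per_residue_decomposition(ens, top, en$complex, en$receptor,
                                    en$ligand,
                                    n_sphere_points = en$sasa_points %||% 240L)
    emit("residue_ledger.tsv",
         function(p) utils::write.table(rl, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    add_metric("hotspots_n", sum(rl$hot_spot))
    if (!is.null(cfg$alanine_scan)) {
      as_res <- alanine_scan(ens, top, en$complex, en$receptor, en$ligand,
                             residues = cfg$alanine_scan$residues,
                             n_sphere_points = en$sasa_points %||% 240L)
      emit("alanine_scan.tsv",
           function(p) utils::write.table(as_res, p, sep = "\t",
                                          quote = FALSE, row.names = FALSE))
      add_metric("alanine_scan_max_ddG", max(abs(as_res$ddG)))
    }
  }

  metrics_df <- if (length(metrics)) do.call(rbind, metrics)
                else data.frame(metric = character(0), mean = numeric(0),
                                sd = numeric(0))
  rownames(metrics_df) <- NULL
  mpath <- file.path(out_dir, "metrics.tsv")
  utils::write.table(metrics_df, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, mpath)
  manifest <- list(
    system = cfg$system,
    package_version = as.character(utils::packageVersion("mdensemble")),
    seed = cfg$seed,
    n_frames = n_frames(ens),
    config = cfg[setdiff(names(cfg), "output_dir")],
    files = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(system = cfg$system, metrics = metrics_df,
                 outputs = c(outputs, man_path), manifest = manifest),
            class = "pipeline_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-system comparison of pipeline reports
#'
#' Aligns the metric tables of two or more reports into one summary with
#' per-system mean +/- SD columns and delta columns versus a designated
#' reference system. Metrics missing from a system appear as NA.
#'
#' @param reports list of `pipeline_report` objects (named or using their
#'   `system` labels).
#' @param reference system label used for the delta columns (default: the
#'   first report).
#' @return data.frame with one row per metric present in any report.
#' @export
compare_systems <- function(reports, reference = NULL) {
  if (length(reports) < 2L) stop("need >= 2 reports to compare")
  labels <- vapply(reports, function(r) r$system, "")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  all_metrics <- unique(unlist(lapply(reports, function(r) r$metrics$metric)))
  common <- Reduce(intersect, lapply(reports, function(r) r$metrics$metric))
  if (!length(common)) stop("disjoint metrics: nothing to compare")
  if (is.null(reference)) reference <- labels[1]
  out <- data.frame(metric = all_metrics)
  for (k in seq_along(reports)) {
    m <- reports[[k]]$metrics
    out[[paste0(labels[k], "_mean")]] <- m$mean[match(all_metrics, m$metric)]
    out[[paste0(labels[k], "_sd")]] <- m$sd[match(all_metrics, m$metric)]
  }
  ref_col <- paste0(reference, "_mean")
  if (!ref_col %in% names(out)) stop("reference system not found: ", reference)
  for (k in seq_along(reports)) {
    if (labels[k] == reference) next
    out[[paste0("delta_", labels[k])]] <-
      out[[paste0(labels[k], "_mean")]] - out[[ref_col]]
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> system %s: %d metrics, %d output files\n",
              x$system, nrow(x$metrics), length(x$outputs)))
  invisible(x)
}
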