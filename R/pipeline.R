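# End-to-end orchestration: aeration -> registration -> mesh/strain -> ROI
# grid -> group statistics. Every stage is a package function; these drivers
# wire them together, log QC metrics, and write the tabular artifacts.

#' Pipeline configuration
#'
#' @param displacement_source `"register"` (estimate the field with
#'   [register_ffd()]) or `"truth"` (inject the analytic phantom field;
#'   phantom cohorts only).
#' @param reg_params Registration parameters ([reg_params()]).
#' @param thresholds HU compartment thresholds ([aeration_thresholds()]).
#' @param n_grid ROI grid size per axis (default 10).
#' @param alpha Significance level for the ROI maps.
#' @param sidedness Alternative for progression tests.
#' @param spi_mode SPI-vs-1 test mode (`"signed_rank"` or `"utest"`).
#' @param p_adjust `"none"` (default) or `"BH"` across cells per family.
#' @param clean_masks Apply speckle cleanup to classified aerated masks.
#' @param write_artifacts Write per-subject NIfTI/VTU/CSV artifacts when an
#'   output directory is given to [run_cohort()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(displacement_source = c("register", "truth"),
                            reg_params = lungstrain::reg_params(),
                            thresholds = aeration_thresholds(),
                            n_grid = 10L, alpha = 0.05,
                            sidedness = "greater", spi_mode = "signed_rank",
                            p_adjust = "none",
                            clean_masks = TRUE, write_artifacts = FALSE) {
  displacement_source <- match.arg(displacement_source)
  if (n_grid < 2) stop("n_grid must be >= 2")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  structure(list(displacement_source = displacement_source,
                 reg_params = reg_params, thresholds = thresholds,
                 n_grid = as.integer(n_grid), alpha = alpha,
                 sidedness = sidedness, spi_mode = spi_mode,
                 p_adjust = p_adjust,
                 clean_masks = clean_masks, write_artifacts = write_artifacts),
            class = "pipeline_config")
}

#' Run the per-subject analysis for one time point
#'
#' EE/EI classification, aerated masks, global metrics, displacement field,
#' tetrahedral mesh, volumetric strain, ROI grid and per-cell statistics.
#'
#' @param subject List with `ee`, `ei` ([ct_image]), `ee_mask`, `ei_mask`
#'   (whole-lung [binary_mask]); optionally `truth` + `spec` (phantoms) and
#'   `group`/`time` labels.
#' @param body_mass_kg Body mass (kg).
#' @param rr_per_min Respiratory rate (1/min).
#' @param config A [pipeline_config()].
#' @param keep_strain_field Keep the per-tet strain table in the result
#'   (large); per-cell statistics are always kept.
#' @return List with `metrics`, `fractions_ee`, `fractions_ei`, `stats`
#'   (per-cell data frame), `grid` occupancy info, `qc`, and optionally
#'   `strain_field` and `field`.
#' @export
run_subject <- function(subject, body_mass_kg, rr_per_min,
                        config = pipeline_config(), keep_strain_field = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (part in c("ee", "ei", "ee_mask", "ei_mask")) {
    if (is.null(subject[[part]])) stop("subject is missing component: ", part)
  }
  am_ee <- classify_aeration(subject$ee, subject$ee_mask, config$thresholds)
  am_ei <- classify_aeration(subject$ei, subject$ei_mask, config$thresholds)
  fr_ee <- compartment_fractions(am_ee)
  fr_ei <- compartment_fractions(am_ei)
  aer_ee <- aerated_mask(am_ee)
  aer_ei <- aerated_mask(am_ei)
  if (config$clean_masks) {
    aer_ee <- clean_mask(aer_ee)
    aer_ei <- clean_mask(aer_ei)
  }
  metrics <- global_metrics(aer_ee, aer_ei, body_mass_kg, rr_per_min)

  field <- if (config$displacement_source == "truth") {
    if (is.null(subject$truth) || is.null(subject$spec)) {
      stop("displacement_source = 'truth' needs a phantom subject with ground truth")
    }
    ground_truth_field(subject$truth, subject$spec)
  } else {
    register_ffd(aer_ei, aer_ee, config$reg_params)
  }

  mesh <- tetrahedralize_mask(aer_ei)
  ref_nodes <- warp_mesh_to_reference(mesh, field)
  sf <- volumetric_strain(mesh, ref_nodes)

  ab_bounds <- axis_partition(sf, "AB", config$n_grid)
  dv_bounds <- axis_partition(sf, "DV", config$n_grid)
  grid <- build_roi_grid(sf, ab_bounds, dv_bounds)
  stats <- roi_weighted_stats(sf, grid)

  qc <- list(
    aerated_volume_ratio_ei_ee = mask_volume(aer_ei) / mask_volume(aer_ee),
    mesh_volume_mm3 = sum(sf$v_ei),
    mesh_matches_mask = abs(sum(sf$v_ei) - mask_volume(aer_ei)) <
      1e-9 * mask_volume(aer_ei),
    reference_volume_over_eelv = sum(sf$v_ee) / metrics$raw_volume_ee_mm3,
    clamped_voxels = am_ee$qc + am_ei$qc,
    occupied_cells = grid$n_occupied)

  out <- list(metrics = metrics, fractions_ee = fr_ee, fractions_ei = fr_ei,
              stats = stats, grid = list(n_occupied = grid$n_occupied,
                                         ab_bounds = ab_bounds,
                                         dv_bounds = dv_bounds),
              qc = qc)
  if (keep_strain_field) {
    out$strain_field <- sf
    out$field <- field
    out$mesh <- mesh
  }
  out
}

#' Run the full cohort analysis
#'
#' Processes every subject at both time points and assembles the group-level
#' outputs: a physiology/metrics table, aeration-fraction table, the
#' per-cell long-format statistics, per-group significance maps for the
#' three test families, and a summary with the percentage-significant
#' figures.
#'
#' @param cohort A cohort from [generate_cohort()] (or a compatible list).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param verbose Print per-subject progress.
#' @return A `cohort_result` list: `metrics`, `aeration`, `roi_stats`,
#'   `maps` (per group), `summary`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), out_dir = NULL,
                       verbose = FALSE) {
  stopifnot(!is.null(cohort$subjects))
  metrics_rows <- list()
  aeration_rows <- list()
  stats_rows <- list()
  spacings <- unique(vapply(cohort$subjects,
                            function(s) s$times[[1]]$ee$spacing, 0))
  if (length(spacings) > 1) stop("mixed grid spacings across subjects")

  for (sid in names(cohort$subjects)) {
    entry <- cohort$subjects[[sid]]
    for (time in names(entry$times)) {
      if (verbose) message(sprintf("processing %s %s", sid, time))
      res <- run_subject(entry$times[[time]],
                         body_mass_kg = entry$body_mass_g / 1000,
                         rr_per_min = unname(entry$rr_per_min[time]),
                         config = config)
      m <- res$metrics
      metrics_rows[[length(metrics_rows) + 1]] <- data.frame(
        subject = sid, group = entry$group, time = time,
        rr_per_min = m$rr_per_min, Vt = m$Vt, Vmin = m$Vmin,
        EELV = m$EELV, EILV = m$EILV,
        global_strain_pct = m$global_strain_pct,
        occupied_cells = res$qc$occupied_cells,
        stringsAsFactors = FALSE)
      for (phase in c("EE", "EI")) {
        fr <- if (phase == "EE") res$fractions_ee else res$fractions_ei
        aeration_rows[[length(aeration_rows) + 1]] <- data.frame(
          subject = sid, group = entry$group, time = time, phase = phase,
          compartment = names(fr), fraction = unname(fr),
          stringsAsFactors = FALSE)
      }
      st <- res$stats
      st$subject <- sid
      st$group <- entry$group
      st$time <- time
      stats_rows[[length(stats_rows) + 1]] <- st
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  aeration <- do.call(rbind, aeration_rows)
  roi_stats <- do.call(rbind, stats_rows)

  groups <- unique(metrics$group)
  maps <- lapply(setNames(groups, groups), function(g) {
    roi_significance_maps(roi_stats[roi_stats$group == g, ],
                          alpha = config$alpha, sidedness = config$sidedness,
                          spi_mode = config$spi_mode, n_grid = config$n_grid,
                          p_adjust = config$p_adjust)
  })

  summary <- list(
    alpha = config$alpha, sidedness = config$sidedness,
    displacement_source = config$displacement_source,
    groups = lapply(maps, function(mp) {
      list(n_testable = mp$n_testable,
           families = lapply(mp[c("strain", "spi", "shi")], function(f) {
             list(n_significant = sum(f$flag), pct = f$pct_significant)
           }))
    }),
    table1 = summarise_metrics(metrics))

  out <- structure(list(metrics = metrics, aeration = aeration,
                        roi_stats = roi_stats, maps = maps, summary = summary),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_artifacts(out, out_dir, config)
  out
}

# mean +/- SEM per group/time, the physiology-table analogue
summarise_metrics <- function(metrics) {
  vars <- c("rr_per_min", "Vt", "Vmin", "EELV", "global_strain_pct")
  out <- list()
  for (g in unique(metrics$group)) {
    for (tm in unique(metrics$time)) {
      sub <- metrics[metrics$group == g & metrics$time == tm, vars, drop = FALSE]
      out[[paste(g, tm, sep = ".")]] <- lapply(sub, function(v) {
        list(mean = mean(v), sem = sd(v) / sqrt(length(v)))
      })
    }
  }
  out
}

write_cohort_artifacts <- function(result, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(result$aeration, file.path(out_dir, "aeration_fractions.csv"),
            row.names = FALSE)
  write.csv(result$roi_stats, file.path(out_dir, "roi_stats_long.csv"),
            row.names = FALSE)
  for (g in names(result$maps)) {
    mp <- result$maps[[g]]
    for (f in c("strain", "spi", "shi")) {
      write.csv(mp[[f]]$p, file.path(out_dir, sprintf("pvalues_%s_%s.csv", g, f)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load one subject's images from a cohort manifest
#'
#' @param manifest Manifest data frame (or path to `manifest.csv`).
#' @param subject_id,time Row selectors.
#' @param root Directory that relative paths resolve against.
#' @return A subject list suitable for [run_subject()].
#' @export
load_subject_images <- function(manifest, subject_id, time, root = ".") {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  out <- list()
  for (phase in c("EE", "EI")) {
    row <- manifest[manifest$subject_id == subject_id & manifest$time == time &
                      manifest$phase == phase, , drop = FALSE]
    if (nrow(row) != 1 || is.na(row$path)) {
      stop(sprintf("missing %s image for subject %s at %s", phase, subject_id, time))
    }
    path <- if (file.exists(row$path)) row$path else file.path(root, row$path)
    vol <- read_nifti_volume(path)
    mask_path <- sub("(^|/)ct_", "\\1mask_", path)
    if (!file.exists(mask_path)) {
      stop(sprintf("missing %s mask for subject %s at %s", phase, subject_id, time))
    }
    msk <- read_nifti_volume(mask_path)
    key <- tolower(phase)
    out[[key]] <- ct_image(vol$data, vol$spacing)
    out[[paste0(key, "_mask")]] <- binary_mask(msk$data > 0, msk$spacing)
  }
  out$group <- manifest$group[manifest$subject_id == subject_id][1]
  out
}

#' ROI heatmap figure
#'
#' Renders a 10 x 10 ROI matrix as a heatmap with the apical-basal axis
#' horizontal and the ventral-dorsal axis vertical, stars on significant
#' cells and void cells blanked.
#'
#' @param mat Numeric ROI matrix (AB x DV, NA = void).
#' @param flags Optional logical matrix of the same shape marking
#'   significant cells.
#' @param title Plot title.
#' @param path Optional output file (written via [ggplot2::ggsave()]).
#' @param fill_name Legend label.
#' @return The ggplot object, invisibly.
#' @export
render_roi_heatmaps <- function(mat, flags = NULL, title = "",
                                path = NULL, fill_name = "value") {
  stopifnot(is.matrix(mat))
  if (!is.null(flags) && !identical(dim(flags), dim(mat))) {
    stop("flags shape must equal matrix shape")
  }
  df <- data.frame(ab = as.vector(row(mat)), dv = as.vector(col(mat)),
                   value = as.vector(mat))
  df$star <- if (is.null(flags)) "" else ifelse(as.vector(flags) & !is.na(df$value), "*", "")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ab, y = .data$dv,
                                         fill = .data$value)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = fill_name) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "apical - basal", y = "ventral - dorsal", title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 5, height = 4.5, dpi = 150)
  invisible(gg)
}

#' Load a run configuration from YAML
#'
#' Reads cohort and pipeline settings from a YAML file with optional
#' `cohort:` and `pipeline:` sections whose keys mirror the arguments of
#' [cohort_config()] and [pipeline_config()]; `pipeline.reg_params` and
#' `pipeline.thresholds` nest the arguments of [reg_params()] and
#' [aeration_thresholds()]. Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return List with `cohort` ([cohort_config()]) and `pipeline`
#'   ([pipeline_config()]) plus the master `seed` (default 1).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  build <- function(fn, args) {
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  pl <- raw$pipeline
  if (!is.null(pl$reg_params)) pl$reg_params <- build(reg_params, pl$reg_params)
  if (!is.null(pl$thresholds)) {
    pl$thresholds <- aeration_thresholds(unlist(pl$thresholds))
  }
  list(cohort = build(cohort_config, raw$cohort),
       pipeline = build(pipeline_config, pl),
       seed = as.integer(raw$seed %||% 1L))
}
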