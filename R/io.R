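#' Write a cohort to disk as NIfTI volumes plus a JSON manifest
#'
#' One `.nii.gz` per subject/repetition (`sub-XX_ses-Y_scan-Z.nii.gz`), an
#' integer label volume (`labels.nii.gz`), and `manifest.json` recording the
#' design, seed, ROI names and file list. Output is byte-stable: rewriting
#' the same cohort produces identical files.
#'
#' @param cohort A `qsm_cohort`.
#' @param dir Output directory (created if needed).
#' @param compress Write `.nii.gz` (default) or plain `.nii`.
#'
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  stopifnot(inherits(cohort, "qsm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  vs <- cohort$maps[[1]][[1]]$voxel_size
  scans_per_session <- cohort$n_repetitions /
    length(unique(cohort$session_of))

  entries <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (r in seq_len(cohort$n_repetitions)) {
      ses <- cohort$session_of[r]
      scan <- r - (ses - 1) * scans_per_session
      file <- sprintf("sub-%02d_ses-%d_scan-%d%s", s, ses, scan, ext)
      img <- RNifti::asNifti(cohort$maps[[s]][[r]]$values)
      RNifti::pixdim(img) <- vs
      RNifti::writeNifti(img, file.path(dir, file))
      entries[[length(entries) + 1L]] <- list(
        subject = s, session = ses, scan = scan, repetition = r, file = file)
    }
  }
  limg <- RNifti::asNifti(cohort$labels)
  RNifti::pixdim(limg) <- vs
  RNifti::writeNifti(limg, file.path(dir, paste0("labels", ext)))

  manifest <- list(
    n_subjects = cohort$n_subjects,
    n_repetitions = cohort$n_repetitions,
    session_of = cohort$session_of,
    roi_names = as.list(cohort$roi_names),
    voxel_size = vs,
    grid_shape = dim(cohort$labels),
    labels_file = paste0("labels", ext),
    seed = cohort$truth$cohort$seed %||% NA,
    maps = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`, the map volumes and the
#'   label volume.
#'
#' @return A `qsm_cohort` (its `truth` element holds only the manifest; the
#'   generating specs are not serialised to volumes).
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop(sprintf("no manifest.json in '%s'", dir), call. = FALSE)
  }
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab_path <- file.path(dir, man$labels_file)
  if (!file.exists(lab_path)) {
    stop(sprintf("label file '%s' not found", man$labels_file),
         call. = FALSE)
  }
  labels <- array(as.integer(round(RNifti::readNifti(lab_path))),
                  man$grid_shape)
  vs <- as.numeric(man$voxel_size)

  maps <- replicate(man$n_subjects,
                    vector("list", man$n_repetitions), simplify = FALSE)
  for (i in seq_len(nrow(man$maps))) {
    e <- man$maps[i, ]
    f <- file.path(dir, e$file)
    if (!file.exists(f)) {
      stop(sprintf("map file '%s' listed in manifest is missing", e$file),
           call. = FALSE)
    }
    img <- RNifti::readNifti(f)
    if (!identical(as.integer(dim(img)), as.integer(dim(labels)))) {
      stop(sprintf("grid mismatch between '%s' and the label map", e$file),
           call. = FALSE)
    }
    vol <- array(as.numeric(img), dim(labels))
    maps[[e$subject]][[e$repetition]] <- qmap(vol, voxel_size = vs)
  }
  structure(
    list(maps = maps, labels = labels,
         roi_names = unlist(man$roi_names),
         session_of = man$session_of,
         n_subjects = man$n_subjects, n_repetitions = man$n_repetitions,
         truth = list(manifest = man)),
    class = "qsm_cohort"
  )
}

#' Default pipeline configuration
#'
#' A complete run configuration: phantom, cohort and acquisition specs,
#' the reconstruction methods to compare (TKD and Tikhonov closed-form
#' inversions applied to the forward field of each map, plus the identity
#' "none"), metric options and statistics options. Serialisable to YAML or
#' JSON with [write_run_config()] and restored by [read_run_config()].
#'
#' @param seed Integer master seed.
#' @param grid_shape Phantom grid; 32^3 by default.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, grid_shape = c(32, 32, 32)) {
  structure(
    list(
      seed = as.integer(seed),
      phantom = list(grid_shape = as.integer(grid_shape)),
      cohort = list(n_subjects = 10L, n_sessions = 2L,
                    scans_per_session = 3L, sigma_b = 0.010,
                    sigma_w = 0.005, voxel_noise_sd = 0.005),
      acquisition = list(echo_times = c(4.61, 9.22, 13.83, 18.44),
                         repetition_time = 27, field_strength = 3,
                         b0_direction = c(0, 0, 1), snr = 100),
      methods = list(
        list(name = "tkd", delta = 0.2),
        list(name = "tikhonov", lambda = 0.05)
      ),
      metrics = list(k1 = 0.01, k2 = 0.001, dynamic_range = 1,
                     window_sigma = 1.5),
      stats = list(n_boot = 1000L, alpha = 0.05, bonferroni = FALSE),
      compress = TRUE
    ),
    class = "run_config"
  )
}

#' Read / write a pipeline configuration
#'
#' YAML or JSON (chosen by file extension). `read_run_config(write_run_config(c))`
#' round-trips the configuration.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config A `run_config` list.
#'
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

validate_run_config <- function(raw) {
  base <- unclass(default_run_config())
  if (is.null(raw$seed)) {
    stop("config field 'seed' is mandatory", call. = FALSE)
  }
  cfg <- utils::modifyList(base, raw)
  # modifyList skips unnamed list entries: take these wholesale when given
  if (!is.null(raw$methods)) cfg$methods <- raw$methods
  if (!is.null(raw$phantom$rois)) cfg$phantom$rois <- raw$phantom$rois
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("n_subjects", "n_sessions", "scans_per_session")) {
    if (is.null(cfg$cohort[[f]]) || cfg$cohort[[f]] < 1) {
      stop(sprintf("config field 'cohort.%s' must be >= 1", f),
           call. = FALSE)
    }
  }
  for (f in c("sigma_b", "sigma_w", "voxel_noise_sd")) {
    if (any(cfg$cohort[[f]] < 0)) {
      stop(sprintf("config field 'cohort.%s' must be >= 0", f),
           call. = FALSE)
    }
  }
  # methods must be a list of {name, parameter}
  for (m in cfg$methods) {
    if (is.null(m$name) ||
        !m$name %in% c("none", "tkd", "tikhonov")) {
      stop("config field 'methods': each entry needs a name in ",
           "{none, tkd, tikhonov}", call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

config_phantom_spec <- function(config) {
  gs <- config$phantom$grid_shape %||% c(32L, 32L, 32L)
  if (!is.null(config$phantom$rois)) {
    phantom_spec(gs, config$phantom$voxel_size %||% c(1.25, 1.25, 1.25),
                 config$phantom$rois,
                 config$phantom$background_chi %||% 0)
  } else {
    default_phantom_spec(gs)
  }
}

config_cohort_spec <- function(config) {
  co <- config$cohort
  cohort_spec(co$n_subjects, co$n_sessions, co$scans_per_session,
              co$sigma_b, co$sigma_w, co$voxel_noise_sd,
              seed = config$seed)
}

#' Simulate a cohort and write it to disk
#'
#' Builds the phantom, samples the repeated cohort under the config's
#' hierarchical variance structure and writes NIfTI volumes, label map and
#' manifest to `out_dir`. Rerunning with the same config yields
#' byte-identical output.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory.
#'
#' @return The cohort, invisibly.
#' @export
qsm_simulate <- function(config, out_dir) {
  config <- as_run_config(config)
  phantom <- config_phantom_spec(config)
  cohort <- sample_cohort(phantom, config_cohort_spec(config))
  write_cohort(cohort, out_dir, compress = isTRUE(config$compress))
  write_run_config(config, file.path(out_dir, "config.json"))
  invisible(cohort)
}

as_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  config
}

# Apply one configured reconstruction method to a chi map: forward-project
# to a field and invert, emulating method-dependent reconstruction error.
apply_method <- function(map, method, kernel) {
  switch(method$name,
    none = map,
    tkd = {
      f <- forward_field(map, kernel)
      q <- tkd_invert(f, kernel, method$delta %||% 0.2)
      q$mask <- map$mask
      q
    },
    tikhonov = {
      f <- forward_field(map, kernel)
      q <- tikhonov_invert(f, kernel, method$lambda %||% 0.05)
      q$mask <- map$mask
      q
    },
    stop(sprintf("unknown method '%s'", method$name), call. = FALSE)
  )
}

method_label <- function(method) {
  switch(method$name,
    none = "none",
    tkd = sprintf("tkd_delta%g", method$delta %||% 0.2),
    tikhonov = sprintf("tikhonov_lambda%g", method$lambda %||% 0.05),
    method$name
  )
}

#' Analyze a repeated cohort: metrics, repeatability records, RANOVA
#'
#' Runs each configured reconstruction method over every map, then
#' computes per-ROI mean tables, voxel-wise pairwise metrics, the full
#' repeatability record (including within-region SD), the
#' between-vs-within-subject variance test per ROI, and a
#' repeated-measures ANOVA across methods. Results are written to
#' `out_dir` as CSV/JSON.
#'
#' @param cohort A `qsm_cohort`, or a directory written by
#'   [qsm_simulate()]/[write_cohort()].
#' @param out_dir Output directory for the report bundle.
#' @param config A `run_config` (or path); defaults to the config stored
#'   alongside a cohort directory, else [default_run_config()].
#' @param voxel_metrics Compute the (more expensive) voxel-wise NRMSE/XSIM
#'   table.
#'
#' @return A list of class `qsm_analysis`: `roi_means`, `records`,
#'   `voxel_metrics`, `voxel_summary`, `ranova` (per ROI),
#'   `between_within` (per ROI and method), `config`.
#' @export
qsm_analyze <- function(cohort, out_dir = NULL, config = NULL,
                        voxel_metrics = TRUE) {
  if (is.character(cohort)) {
    if (is.null(config)) {
      cfg_path <- file.path(cohort, "config.json")
      if (file.exists(cfg_path)) config <- cfg_path
    }
    cohort <- read_cohort(cohort)
  }
  config <- if (is.null(config)) default_run_config() else
    as_run_config(config)

  vs <- cohort$maps[[1]][[1]]$voxel_size
  kernel <- dipole_kernel(dim(cohort$labels), vs,
                          config$acquisition$b0_direction %||% c(0, 0, 1))
  labels <- cohort$labels
  roi_labels <- sort(unique(labels[labels > 0]))

  tables <- list()
  sig_r <- list()
  vox <- list()
  method_labs <- make.unique(
    vapply(config$methods, method_label, character(1)))
  for (mi in seq_along(config$methods)) {
    m <- config$methods[[mi]]
    lab <- method_labs[mi]
    recon <- cohort
    recon$maps <- lapply(cohort$maps, function(reps) {
      lapply(reps, apply_method, method = m, kernel = kernel)
    })
    tables[[lab]] <- roi_means(recon, roi_labels, method = lab)
    # within-region SD: mean over all maps of the per-map ROI voxel SD
    sig_r[[lab]] <- dplyr::bind_rows(lapply(roi_labels, function(l) {
      sds <- unlist(lapply(recon$maps, function(reps) {
        vapply(reps, function(q) sigma_r(q, labels == l), numeric(1))
      }))
      roi_tag <- cohort$roi_names[as.character(l)] %||% as.character(l)
      tibble::tibble(roi = unname(roi_tag), method = lab,
                     sigma_r = mean(sds))
    }))
    if (voxel_metrics) {
      vm <- pairwise_voxel_metrics(
        recon, roi_labels,
        dynamic_range = config$metrics$dynamic_range %||% 1,
        k1 = config$metrics$k1 %||% 0.01,
        k2 = config$metrics$k2 %||% 0.001,
        window_sigma = config$metrics$window_sigma %||% 1.5)
      vm$method <- lab
      vox[[lab]] <- vm
    }
  }
  all_means <- dplyr::bind_rows(tables)
  sig_r_table <- dplyr::bind_rows(sig_r)
  records <- repeatability_summary(
    all_means, n_boot = config$stats$n_boot %||% 1000L,
    seed = config$seed, sigma_r_table = sig_r_table)

  # between- vs within-subject variance per ROI and method
  bw <- dplyr::bind_rows(lapply(split(
    all_means, list(all_means$roi, all_means$method), drop = TRUE),
    function(sub) {
      r <- between_vs_within_test(roi_matrix(sub))
      tibble::tibble(roi = sub$roi[1], method = sub$method[1],
                     f = r$f, df1 = r$df[1], df2 = r$df[2], p = r$p,
                     degenerate = r$degenerate)
    }))

  # RM-ANOVA across methods, per ROI, on subject means
  ranova <- NULL
  if (length(config$methods) >= 2L) {
    ranova <- lapply(split(all_means, all_means$roi), function(sub) {
      wide <- sub |>
        dplyr::group_by(.data$subject, .data$method) |>
        dplyr::summarise(chi_ppm = mean(.data$chi_ppm), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "method", values_from = "chi_ppm")
      rm_anova(as.matrix(wide[, -1]), alpha = config$stats$alpha %||% 0.05)
    })
  }

  voxel_table <- if (length(vox)) dplyr::bind_rows(vox) else NULL
  res <- structure(
    list(roi_means = all_means, records = records,
         voxel_metrics = voxel_table,
         voxel_summary = if (!is.null(voxel_table))
           summarize_voxel_metrics(voxel_table) else NULL,
         ranova = ranova, between_within = bw, config = config),
    class = "qsm_analysis"
  )
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_stable(res$roi_means, file.path(out_dir, "roi_means.csv"))
  write_csv_stable(res$records, file.path(out_dir, "repeatability_records.csv"))
  if (!is.null(res$voxel_metrics)) {
    write_csv_stable(res$voxel_metrics, file.path(out_dir, "voxel_metrics.csv"))
    write_csv_stable(res$voxel_summary,
                     file.path(out_dir, "voxel_metrics_summary.csv"))
  }
  report <- list(
    records = res$records,
    between_within = res$between_within,
    ranova = lapply(res$ranova, unclass)
  )
  jsonlite::write_json(report, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Compare reconstruction methods on one analyzed cohort
#'
#' Produces the method-comparison report: per-ROI pairwise mean-difference
#' matrices in ppb with paired-t significance flags, the per-method ICC
#' table with bootstrap CIs, and a classification summary.
#'
#' @param analysis A `qsm_analysis` from [qsm_analyze()], or one or more
#'   analysis directories (each containing `roi_means.csv`); multiple
#'   directories are merged and must share subjects and repetitions.
#' @param out_dir Optional directory for `comparison.json` and the pairwise
#'   CSVs.
#' @param alpha Significance level for the pairwise flags.
#' @param bonferroni Bonferroni-correct the pairwise p-values.
#' @param n_boot,seed Bootstrap settings for the ICC table when recomputed
#'   from CSV input.
#'
#' @return A list of class `qsm_comparison`: `pairwise`, `icc_table`,
#'   `classification`.
#' @export
qsm_compare <- function(analysis, out_dir = NULL, alpha = 0.05,
                        bonferroni = FALSE, n_boot = 1000L, seed = 1L) {
  if (is.character(analysis)) {
    tabs <- lapply(analysis, function(d) {
      f <- file.path(d, "roi_means.csv")
      if (!file.exists(f)) {
        stop(sprintf("'%s' does not contain roi_means.csv", d),
             call. = FALSE)
      }
      tibble::as_tibble(utils::read.csv(f))
    })
    shapes <- lapply(tabs, function(t)
      list(s = sort(unique(t$subject)), r = sort(unique(t$repetition))))
    for (i in seq_along(shapes)[-1]) {
      if (!identical(shapes[[i]], shapes[[1]])) {
        stop("analysis directories do not share one cohort design",
             call. = FALSE)
      }
    }
    table <- dplyr::bind_rows(tabs)
    records <- repeatability_summary(table, n_boot = n_boot, seed = seed)
  } else {
    stopifnot(inherits(analysis, "qsm_analysis"))
    table <- analysis$roi_means
    records <- analysis$records
  }

  pw <- pairwise_method_diffs(table, alpha = alpha,
                              bonferroni = bonferroni)
  icc_table <- dplyr::select(records, "roi", "method", "icc", "icc_lower",
                             "icc_upper", "classification")
  cls <- icc_table |>
    dplyr::count(.data$method, .data$classification, name = "n_rois")

  res <- structure(
    list(pairwise = pw, icc_table = icc_table, classification = cls),
    class = "qsm_comparison"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        pairwise = lapply(pw, function(m) list(
          methods = rownames(m$diff_ppb),
          diff_ppb = m$diff_ppb, p = m$p,
          not_significant = m$not_significant)),
        icc_table = icc_table,
        classification = cls
      ),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows",
      matrix = "rowmajor")
    write_csv_stable(icc_table, file.path(out_dir, "icc_table.csv"))
  }
  res
}
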