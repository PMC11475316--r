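#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]: a cohort of
#' phantom samples (one per tissue class by default), the acquisition
#' geometry, attenuation and elastography parameters, ROI sampling settings
#' and the diagnostic contrasts. Every source of randomness derives from
#' `seed`; there is no hidden global state, so a fixed configuration yields
#' byte-identical outputs.
#'
#' @param seed Master integer seed.
#' @param classes Tissue classes to simulate (reference class codes).
#' @param n_samples_per_class Phantom samples per class.
#' @param width_px,depth_px Phantom geometry (smaller values keep desk-scale
#'   runs fast).
#' @return A nested configuration list (JSON-serializable).
#' @export
default_config <- function(seed = 1L,
                           classes = c("proliferative", "non_atypical", "EIN", "EC_low"),
                           n_samples_per_class = 1L,
                           width_px = 128L, depth_px = 256L) {
  list(
    seed = as.integer(seed),
    samples = unlist(lapply(classes, function(cl) {
      lapply(seq_len(n_samples_per_class), function(i) {
        list(sample_id = sprintf("%s_%02d", cl, i), tissue_class = cl)
      })
    }), recursive = FALSE),
    phantom = list(width_px = as.integer(width_px), depth_px = as.integer(depth_px),
                   silicone_px = 48L, tissue_px = as.integer(depth_px) - 56L,
                   noise_floor = 1e-4, E_ref = 100, k = 50),
    attenuation = list(noise = "known", smooth_lateral = 16L, tail_frac = 0.01,
                       vmax = 12),
    oce = list(lag = 4L, window = c(8L, 8L), stress_level = 1, stress_window = 0.5,
               stress_steps = seq(0, 1.68, by = 0.12), vmax = 600),
    roi = list(n_regions = 10L, region_shape = c(10L, 10L)),
    contrasts = list(
      list(name = "EC_vs_nontumor_stiffness", modality = "stiffness",
           positive = c("EC_low", "EC_high", "EC_clear", "EC_serous"),
           negative = c("proliferative", "secretory", "atrophic", "non_atypical", "EIN"),
           direction = "higher"),
      list(name = "EIN_vs_benign_stiffness", modality = "stiffness",
           positive = "EIN",
           negative = c("proliferative", "secretory", "atrophic", "non_atypical"),
           direction = "higher")),
    threshold_policy = "youden",
    write_images = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks every parameter range before any stage runs; the first offending
#' parameter is named in the error.
#'
#' @param config Configuration list (see [default_config()]) or the path of
#'   a JSON configuration file.
#' @return The validated (normalized) configuration, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stopf("'config' must be a list or a JSON file path")
  check_scalar(config$seed %||% NA, "seed")
  if (!length(config$samples)) stopf("'samples' must list at least one sample")
  known <- endometrial_reference()$morphology
  for (s in config$samples) {
    if (is.null(s$sample_id)) stopf("'samples': every sample needs a sample_id")
    if (is.null(s$tissue_class) || !s$tissue_class %in% known) {
      stopf("'samples': unknown tissue_class '%s' for sample '%s'",
            s$tissue_class %||% "<missing>", s$sample_id)
    }
  }
  ph <- config$phantom
  check_scalar(ph$width_px %||% NA, "phantom$width_px", 16)
  check_scalar(ph$depth_px %||% NA, "phantom$depth_px", 32)
  check_scalar(ph$silicone_px %||% NA, "phantom$silicone_px", 16)
  check_scalar(ph$E_ref %||% NA, "phantom$E_ref", 0, strict = TRUE)
  check_scalar(ph$noise_floor %||% NA, "phantom$noise_floor", 0)
  at <- config$attenuation
  check_scalar(at$smooth_lateral %||% NA, "attenuation$smooth_lateral", 0)
  check_scalar(at$tail_frac %||% NA, "attenuation$tail_frac", 0)
  check_scalar(at$vmax %||% NA, "attenuation$vmax", 0, strict = TRUE)
  oce <- config$oce
  check_scalar(oce$lag %||% NA, "oce$lag", 1)
  check_scalar(oce$stress_level %||% NA, "oce$stress_level", 0, strict = TRUE)
  check_scalar(oce$stress_window %||% NA, "oce$stress_window", 0, strict = TRUE)
  if (length(oce$stress_steps) < 2L || oce$stress_steps[1] != 0 ||
      any(diff(oce$stress_steps) <= 0)) {
    stopf("oce$stress_steps must start at 0 and be strictly increasing")
  }
  roi <- config$roi
  check_scalar(roi$n_regions %||% NA, "roi$n_regions", 1)
  if (length(roi$region_shape) != 2L || any(roi$region_shape < 1)) {
    stopf("roi$region_shape must be c(rows, cols) >= 1")
  }
  for (ct in config$contrasts) {
    contrast_spec(ct$positive, ct$negative, ct$modality, ct$direction, ct$name)
  }
  if (!config$threshold_policy %in% c("youden", "closest01")) {
    stopf("threshold_policy must be 'youden' or 'closest01'")
  }
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full quantitative multimodal OCT pipeline
#'
#' For every configured sample: generate the class-matched phantom stack and
#' compression series, compensate and convert the two polarization channels
#' to attenuation maps, estimate the stiffness map, and sample measurement
#' regions in the tissue layer. The pooled measurement table then feeds the
#' descriptive statistics, the pairwise Mann-Whitney/Bonferroni comparison
#' matrix and the configured ROC contrasts.
#'
#' Outputs written to `out_dir`: `measurement_table.csv`, `descriptives.csv`,
#' `comparisons.csv`, `roc_points_<name>.csv`, `roc_summary.json` and a
#' `provenance.json` record (config hash, package version, seeds). With
#' `write_images = TRUE`, rendered attenuation/stiffness PNG maps are
#' written as well. A failing stage aborts with the stage named; outputs
#' written so far are retained next to a `FAILED_<stage>` marker file.
#'
#' @param config See [default_config()] / [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the measurement table, descriptives,
#'   comparison matrix, ROC results and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("mmoct_run_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on.exit({
    if (!identical(stage, "done")) {
      file.create(file.path(out_dir, paste0("FAILED_", stage)))
      message(sprintf("pipeline aborted in stage '%s'; partial outputs retained in %s",
                      stage, out_dir))
    }
  })
  rows <- list()
  maps <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    sample_seed <- config$seed + 1000L * i
    stage <- paste0("phantom:", s$sample_id)
    spec <- phantom_spec_from_reference(
      s$tissue_class, k = config$phantom$k, E_ref = config$phantom$E_ref,
      silicone_px = config$phantom$silicone_px,
      tissue_px = config$phantom$tissue_px,
      width_px = config$phantom$width_px, depth_px = config$phantom$depth_px,
      noise_floor = config$phantom$noise_floor, seed = sample_seed)
    gen <- generate_cpoct_stack(spec)
    oce_gen <- generate_compression_series(spec, config$oce$stress_steps,
                                           max_lag_px = config$oce$lag)
    stage <- paste0("attenuation:", s$sample_id)
    nf <- if (identical(config$attenuation$noise, "known")) spec$noise_floor else "auto"
    corrected <- compensate_signal(gen$stack, noise_floor = nf)
    att <- lapply(c(co = "co", cross = "cross"), function(ch) {
      estimate_attenuation(corrected, channel = ch,
                           smooth_lateral = config$attenuation$smooth_lateral,
                           tail_frac = config$attenuation$tail_frac)
    })
    stage <- paste0("elastography:", s$sample_id)
    stiff <- estimate_stiffness(oce_gen$series, lag = config$oce$lag,
                                window = config$oce$window,
                                stress_level = config$oce$stress_level,
                                stress_window = config$oce$stress_window)
    stage <- paste0("roi:", s$sample_id)
    tissue_rows <- which(rowSums(oce_gen$series$tissue_mask) > 0)
    # stay clear of estimator edge transients at the layer interfaces
    pad <- config$oce$lag + max(config$oce$window)
    mask <- matrix(FALSE, spec$depth_px, spec$width_px)
    keep <- tissue_rows[tissue_rows >= min(tissue_rows) + pad &
                          tissue_rows <= max(tissue_rows) - pad]
    mask[keep, ] <- TRUE
    for (mod in c("att_co", "att_cross", "stiffness")) {
      m <- switch(mod, att_co = att$co, att_cross = att$cross, stiffness = stiff)
      # place regions where the tissue mask and the map's validity overlap
      rois <- sample_rois(m, mask & m$valid_mask, n_regions = config$roi$n_regions,
                          region_shape = config$roi$region_shape,
                          seed = sample_seed + match(mod, c("att_co", "att_cross", "stiffness")))
      rows[[length(rows) + 1L]] <- measurement_rows(rois, s$sample_id, s$tissue_class, mod)
    }
    maps[[s$sample_id]] <- list(att_co = att$co, att_cross = att$cross, stiffness = stiff)
    if (isTRUE(config$write_images)) {
      render_map(att$co, vmax = config$attenuation$vmax,
                 file = file.path(out_dir, paste0(s$sample_id, "_att_co.png")))
      render_map(att$cross, vmax = config$attenuation$vmax,
                 file = file.path(out_dir, paste0(s$sample_id, "_att_cross.png")))
      render_stiffness(stiff, vmax = config$oce$vmax,
                       file = file.path(out_dir, paste0(s$sample_id, "_stiffness.png")))
    }
  }

  stage <- "statistics"
  table <- do.call(rbind, rows)
  write.csv(table, file.path(out_dir, "measurement_table.csv"), row.names = FALSE)
  desc <- do.call(rbind, lapply(split(table, list(table$tissue_class, table$modality),
                                      drop = TRUE), function(g) {
    d <- describe_mq(g$value, digits = if (g$modality[1] == "stiffness") 0 else 2)
    data.frame(tissue_class = g$tissue_class[1], modality = g$modality[1],
               n = sum(is.finite(g$value)), median = d$median, q1 = d$q1,
               q3 = d$q3, label = d$label, stringsAsFactors = FALSE)
  }))
  desc <- desc[order(desc$modality, desc$tissue_class), ]
  write.csv(desc, file.path(out_dir, "descriptives.csv"), row.names = FALSE)
  comparisons <- NULL
  if (length(unique(table$tissue_class)) >= 2L) {
    comparisons <- pairwise_mann_whitney(table)
    write.csv(as.data.frame(comparisons), file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
  }

  stage <- "diagnostics"
  rocs <- list()
  for (ct in config$contrasts) {
    cs <- contrast_spec(ct$positive, ct$negative, ct$modality, ct$direction, ct$name)
    present <- unique(table$tissue_class)
    if (!any(cs$positive %in% present) || !any(cs$negative %in% present)) next
    r <- roc_analysis(table, cs, policy = config$threshold_policy)
    rocs[[cs$name]] <- r
    write.csv(r$points, file.path(out_dir, paste0("roc_points_", cs$name, ".csv")),
              row.names = FALSE)
  }
  if (length(rocs)) {
    jsonlite::write_json(
      lapply(rocs, function(r) list(auc = r$auc, threshold = r$chosen$threshold,
                                    se = r$chosen$se, sp = r$chosen$sp,
                                    n_pos = r$n_pos, n_neg = r$n_neg)),
      file.path(out_dir, "roc_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  stage <- "provenance"
  jsonlite::write_json(
    list(config_hash = config_hash(config), package = "mmoct",
         version = as.character(utils::packageVersion("mmoct")),
         seed = config$seed,
         sample_seeds = config$seed + 1000L * seq_along(config$samples)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  stage <- "done"
  invisible(list(table = table, descriptives = desc, comparisons = comparisons,
                 rocs = rocs, maps = maps, out_dir = out_dir))
}
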