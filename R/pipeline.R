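#' Pipeline configuration
#'
#' Collects every numeric choice of the per-scan pipeline in one list so a
#' scan report is fully determined by its inputs plus this configuration. The
#' report records an MD5 digest of the configuration; changing any value
#' changes the digest.
#'
#' @param n_slices Number of analysis slices (default 18).
#' @param grav_extent `"per-slice"` or `"global"` gravitational extent.
#' @param hyper_upper,nonaer_lower Aeration compartment bounds, HU.
#' @param air_threshold,min_component_volume_ml,closing_radius_mm Segmentation
#'   parameters used only when no external mask is supplied.
#' @return A named list of class `scan_config`.
#' @export
scan_config <- function(n_slices = 18L, grav_extent = "per-slice",
                        hyper_upper = -800, nonaer_lower = -100,
                        air_threshold = -300, min_component_volume_ml = 50,
                        closing_radius_mm = 3) {
  structure(
    list(
      n_slices = as.integer(n_slices), grav_extent = grav_extent,
      hyper_upper = hyper_upper, nonaer_lower = nonaer_lower,
      air_threshold = air_threshold,
      min_component_volume_ml = min_component_volume_ml,
      closing_radius_mm = closing_radius_mm
    ),
    class = "scan_config"
  )
}

.config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "focalindex_stage_error", parent = e
    )
  })
}

#' Run the full per-scan analysis
#'
#' Orchestrates the chain ingest, (segment), clip, slice selection,
#' nine-region partition, HU profiles, aeration compartments, focal index and
#' gas/weight quantitation for one scan. The run is deterministic: identical
#' inputs and configuration reproduce the report bit-exactly.
#'
#' @param ct A [ct_volume()] or a path readable by [read_ct()].
#' @param mask Optional [lung_mask()] or NIfTI path. When omitted the scan is
#'   segmented with [segment_lungs()] (an external mask always takes
#'   precedence).
#' @param config A [scan_config()].
#' @return A `scan_report`: list with `source_id`, `focal_index`,
#'   `overlap_percent`, `aeration` (9-row tibble), `roi_counts`,
#'   `slice_indices`, `quantitation` (totals + per-slice tibble), `profiles`,
#'   `clipped_count`, `warnings`, `config`, `config_digest` and `version`.
#' @export
run_scan <- function(ct, mask = NULL, config = scan_config()) {
  volume <- .stage("ingest", if (inherits(ct, "ct_volume")) ct else read_ct(ct))
  mask <- .stage("segment", {
    if (is.null(mask)) {
      segment_lungs(volume,
        air_threshold = config$air_threshold,
        min_component_volume_ml = config$min_component_volume_ml,
        closing_radius_mm = config$closing_radius_mm
      )
    } else if (inherits(mask, "lung_mask")) {
      mask
    } else {
      read_lung_mask(mask)
    }
  })
  warnings <- character(0)
  clipped <- .stage("clip", clip_hu(volume, mask))
  if (attr(clipped, "clipped_count") > 0) {
    warnings <- c(warnings, sprintf(
      "%d in-mask voxels clipped to [-1000, 100] HU.", attr(clipped, "clipped_count")
    ))
  }
  selection <- .stage("slice-selection", select_slices(volume, mask, config$n_slices))
  rmap <- .stage("regions", withCallingHandlers(
    build_region_map(volume, mask, selection, extent = config$grav_extent),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  ))
  profiles <- .stage("profiles", hu_profiles(clipped, mask, rmap))
  aeration <- .stage("aeration", dplyr::left_join(
    aeration_summary(profiles,
      hyper_upper = config$hyper_upper,
      nonaer_lower = config$nonaer_lower
    ),
    roi_table()[, c("roi_id", "roi_code")],
    by = "roi_id"
  ))
  fi <- .stage("focal-index", focal_index(profiles))
  quant <- .stage("quantitation", {
    has_lung <- which(apply(mask, 1, any))
    per_slice <- slice_quantities(clipped, mask, selection$indices)
    whole_lung_quantitation(per_slice, has_lung)
  })
  structure(
    list(
      source_id = volume$source_id,
      focal_index = fi$value,
      overlap_percent = fi$overlap_percent,
      aeration = aeration,
      roi_counts = rmap$counts,
      slice_indices = selection$indices,
      quantitation = quant,
      profiles = profiles,
      clipped_count = attr(clipped, "clipped_count"),
      warnings = warnings,
      config = config,
      config_digest = .config_digest(config),
      version = as.character(utils::packageVersion("focalindex"))
    ),
    class = "scan_report"
  )
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<scan_report '%s'>\n  focal index %.2f (overlap %.2f%%)\n",
      "  gas %.1f ml, weight %.1f g\n  %d warnings, config %s\n"
    ),
    x$source_id, x$focal_index, x$overlap_percent,
    x$quantitation$gas_volume_ml, x$quantitation$lung_weight_g,
    length(x$warnings), substr(x$config_digest, 1, 8)
  ))
  invisible(x)
}

#' @export
glance.scan_report <- function(x, ...) {
  ae <- x$aeration
  tibble(
    source_id = x$source_id,
    focal_index = x$focal_index,
    overlap_percent = x$overlap_percent,
    dorsal_diaphragmatic_nonaer_percent =
      ae$nonaer_percent[ae$roi_id == "dorsal_diaphragmatic"],
    ventral_apical_hyper_percent =
      ae$hyper_percent[ae$roi_id == "ventral_apical"],
    total_gas_ml = x$quantitation$gas_volume_ml,
    lung_weight_g = x$quantitation$lung_weight_g
  )
}

#' Serialize a scan report to JSON
#'
#' Writes a self-describing, machine-readable report (scores, aeration table,
#' region counts, quantitation, warnings, config digest, version). Numbers are
#' written at full precision so reruns on identical inputs are byte-identical.
#'
#' @param report A [run_scan()] result.
#' @param path Output path.
#' @param profiles Include the full 9 x 220 profile table (default FALSE).
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(report, path, profiles = FALSE) {
  stopifnot(inherits(report, "scan_report"))
  out <- list(
    source_id = report$source_id,
    focal_index = report$focal_index,
    overlap_percent = report$overlap_percent,
    aeration = report$aeration,
    roi_counts = report$roi_counts[, c("roi_code", "roi_id", "n_voxels")],
    slice_indices = report$slice_indices,
    gas_volume_ml = report$quantitation$gas_volume_ml,
    lung_weight_g = report$quantitation$lung_weight_g,
    per_slice = report$quantitation$per_slice,
    clipped_count = report$clipped_count,
    warnings = report$warnings,
    config = unclass(report$config),
    config_digest = report$config_digest,
    version = report$version
  )
  if (profiles) out$profiles <- report$profiles
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Run the analysis over a cohort and compute the study statistics
#'
#' Applies [run_scan()] to every scan of a manifest and assembles the cohort
#' table (focal index, regional aeration, gas, weight, covariates), then runs
#' the correlation battery (focal index against dorsal-diaphragmatic
#' non-aeration, ventral-apical hyperaeration, total gas, lung weight and -
#' when provided - fluid balance) and the ventilatory-settings sensitivity
#' regression when those covariates are present.
#'
#' @param manifest A data frame with columns `source_id` and either `ct_path`
#'   (+ optional `mask_path`) or a list-column `scan` of
#'   `list(volume, mask)` pairs; optional covariate columns
#'   `fluid_balance_ml`, `peep_cmH2O`, `rr_per_min`, `vt_per_pbw_ml_kg`.
#' @param config A [scan_config()].
#' @return A `cohort_result`: list with `cohort` (one row per scan),
#'   `correlations` (tibble), `regression` (a [sensitivity_regression()] fit
#'   or `NULL`) and `reports`.
#' @export
run_cohort <- function(manifest, config = scan_config()) {
  manifest <- as_tibble(manifest)
  if (!"source_id" %in% names(manifest)) {
    abort("Manifest needs a `source_id` column.", class = "focalindex_manifest_error")
  }
  if ("ct_path" %in% names(manifest)) {
    missing_ct <- manifest$source_id[!file.exists(manifest$ct_path)]
    if (length(missing_ct)) {
      abort(
        sprintf("Missing CT inputs for: %s.", paste(missing_ct, collapse = ", ")),
        class = "focalindex_manifest_error"
      )
    }
  } else if (!"scan" %in% names(manifest)) {
    abort("Manifest needs `ct_path` or a `scan` list-column.",
      class = "focalindex_manifest_error"
    )
  }
  reports <- lapply(seq_len(nrow(manifest)), function(i) {
    if ("scan" %in% names(manifest)) {
      scan <- manifest$scan[[i]]
      rep <- run_scan(scan$volume, scan$mask, config = config)
    } else {
      mask <- if ("mask_path" %in% names(manifest)) manifest$mask_path[i] else NULL
      rep <- run_scan(manifest$ct_path[i], mask, config = config)
    }
    rep$source_id <- as.character(manifest$source_id[i])
    rep
  })
  cohort <- dplyr::bind_rows(lapply(reports, glance))
  covars <- intersect(
    c("fluid_balance_ml", "peep_cmH2O", "rr_per_min", "vt_per_pbw_ml_kg"),
    names(manifest)
  )
  if (length(covars)) {
    cohort <- dplyr::left_join(
      cohort,
      dplyr::mutate(
        manifest[, c("source_id", covars)],
        source_id = as.character(.data$source_id)
      ),
      by = "source_id"
    )
  }
  # sort by source_id so statistics are invariant to manifest row order
  cohort <- dplyr::arrange(cohort, .data$source_id)

  pairs <- c(
    dorsal_diaphragmatic_nonaer_percent = "dorsal_diaphragmatic_nonaer_percent",
    ventral_apical_hyper_percent = "ventral_apical_hyper_percent",
    total_gas_ml = "total_gas_ml",
    lung_weight_g = "lung_weight_g",
    fluid_balance_ml = "fluid_balance_ml"
  )
  pairs <- pairs[pairs %in% names(cohort)]
  if (stats::sd(cohort$focal_index) == 0) {
    abort("Correlation battery is undefined: the focal index has zero variance.",
      class = "focalindex_degenerate_error"
    )
  }
  correlations <- purrr::map_dfr(pairs, function(v) {
    res <- tryCatch(
      pearson_with_ci(cohort, "focal_index", !!rlang::sym(v)),
      focalindex_degenerate_error = function(e) {
        warn(sprintf("Correlation with '%s' undefined (zero variance); reported as NA.", v))
        tibble(
          estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
          p_value = NA_real_, n = sum(is.finite(cohort[[v]])), method = "pearson"
        )
      }
    )
    res$variable <- v
    res
  })
  correlations <- correlations[, c("variable", "estimate", "conf_low", "conf_high", "p_value", "n", "method")]

  regression <- NULL
  if (all(c("peep_cmH2O", "rr_per_min", "vt_per_pbw_ml_kg") %in% names(cohort))) {
    regression <- sensitivity_regression(cohort)
  }
  structure(
    list(
      cohort = cohort, correlations = correlations,
      regression = regression, reports = reports
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d scans\n", nrow(x$cohort)))
  print(x$correlations)
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
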